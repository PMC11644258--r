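#' Lightweight differential enrichment statistics
#'
#' Computes per-gene endosperm vs whole-seed enrichment statistics from
#' raw counts: log2 fold change of library-size-normalized group means
#' (CPM with a pseudocount) and a Welch two-sample t-test on
#' log2(CPM + 1). This is a deliberately simple, dependency-free test for
#' desk-scale and synthetic data; externally computed (log2fc, p) tables
#' from a negative-binomial framework can be substituted wherever an
#' enrichment table is consumed.
#'
#' FDR-adjusted p-values are left unset; fill them with [bh_adjust()]
#' before calling [classify_enriched()].
#'
#' @param counts a [count_set] with at least 2 samples per group.
#' @param pseudocount added to group-mean CPM before the ratio (default
#'   0.5) to stabilize log fold changes of low counts.
#' @return A data.frame with columns `gene`, `log2fc`, `p_raw`, `p_fdr`
#'   (NA), `enriched` (NA).
#' @export
differential_enrichment <- function(counts, pseudocount = 0.5) {
  if (!inherits(counts, "count_set")) stop("'counts' must be a count_set")
  grp <- counts$samples$group
  if (sum(grp == "endosperm") < 2L || sum(grp == "whole_seed") < 2L)
    stop("each group needs at least 2 samples (variance undefined otherwise)")
  m <- counts$counts
  libsize <- colSums(m)
  if (any(libsize == 0)) stop("a sample has zero total counts")
  cpm <- t(t(m) / libsize) * 1e6
  a <- cpm[, grp == "endosperm", drop = FALSE]
  b <- cpm[, grp == "whole_seed", drop = FALSE]
  log2fc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  la <- log2(a + 1)
  lb <- log2(b + 1)
  p_raw <- vapply(seq_len(nrow(m)), function(i) {
    xa <- la[i, ]
    xb <- lb[i, ]
    if (sd(xa) == 0 && sd(xb) == 0) {
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    }
    t.test(xa, xb)$p.value
  }, numeric(1))
  data.frame(gene = rownames(m), log2fc = log2fc, p_raw = p_raw,
             p_fdr = NA_real_, enriched = NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (a validated wrapper around
#' `stats::p.adjust(method = "BH")`): sort ascending, multiply by m/rank,
#' enforce monotonicity from the largest down, cap at 1, return in input
#' order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Classify endosperm-enriched genes
#'
#' A gene is enriched when its log2 fold change strictly exceeds
#' `lfc_threshold` and its FDR-adjusted p-value is strictly below
#' `fdr_threshold`. Defaults are the standard enrichment thresholds of
#' log2FC > 1.5 at FDR < 0.01.
#'
#' @param records enrichment data.frame as returned by
#'   [differential_enrichment()], with `p_fdr` populated.
#' @param lfc_threshold log2 fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.01).
#' @return Character vector of enriched gene ids.
#' @export
classify_enriched <- function(records, lfc_threshold = 1.5,
                              fdr_threshold = 0.01) {
  if (!all(c("gene", "log2fc", "p_fdr") %in% names(records)))
    stop("'records' must have gene, log2fc and p_fdr columns")
  if (any(is.na(records$p_fdr)))
    stop("p_fdr is not populated; run bh_adjust() first")
  flag <- records$log2fc > lfc_threshold & records$p_fdr < fdr_threshold
  records$gene[flag]
}

# Normalizing constant for the per-value entropy score: the maximum of
# -q * log2(q) over q in (0, 1], attained at q = 1/e.
MSE_NORM <- log2(exp(1)) / exp(1)

#' Per-time-point mean expression profiles
#'
#' Averages replicates within each time point, the time-course summary
#' used by both the entropy filter and sign assignment.
#'
#' @param expr an [expression_set].
#' @return Numeric matrix, genes x time points (columns ordered and named
#'   by time).
#' @export
time_course_means <- function(expr) {
  if (!inherits(expr, "expr_set")) stop("'expr' must be an expr_set")
  tp <- sort(unique(expr$samples$time_dap))
  out <- vapply(tp, function(t) {
    rowMeans(expr$values[, expr$samples$time_dap == t, drop = FALSE])
  }, numeric(nrow(expr$values)))
  colnames(out) <- as.character(tp)
  rownames(out) <- rownames(expr$values)
  out
}

#' Modified Shannon entropy filter for dynamic specificity
#'
#' Scores each expression value of a gene's time profile by its
#' contribution to the profile's Shannon entropy: with p_t the value's
#' share of the profile total, the per-value entropy e_t = -p_t log2(p_t)
#' is normalized by its maximum over all shares (log2(e)/e, attained at
#' p = 1/e) to give a scale-free score in [0, 1]. A score below
#' `outlier_threshold` marks the value as an outlier (the profile is
#' concentrated at, or absent from, that time point), and a gene is
#' retained if any time point is an outlier — i.e. the profile is
#' dynamically specific rather than flat. All-zero profiles are excluded.
#'
#' @param profiles genes x time-points matrix of non-negative per-time
#'   means (see [time_course_means()]), at least 2 columns.
#' @param outlier_threshold score below which a value is an outlier
#'   (default 0.30).
#' @return Character vector of retained gene ids.
#' @export
mse_filter <- function(profiles, outlier_threshold = 0.30) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) stop("at least 2 time points required")
  if (any(profiles < 0)) stop("negative expression means")
  if (is.null(rownames(profiles))) stop("'profiles' must have gene rownames")
  tot <- rowSums(profiles)
  keep <- rep(FALSE, nrow(profiles))
  pos <- tot > 0
  if (any(pos)) {
    p <- profiles[pos, , drop = FALSE] / tot[pos]
    e <- -p * log2(p)
    e[p == 0] <- 0
    s <- e / MSE_NORM
    keep[pos] <- apply(s < outlier_threshold, 1, any)
  }
  rownames(profiles)[keep]
}

#' Per-value entropy scores of a single profile
#'
#' The normalized per-value scores underlying [mse_filter()]; exposed for
#' inspection and plotting.
#'
#' @param means non-negative numeric vector (a gene's per-time-point
#'   means).
#' @return Numeric vector of scores in [0, 1]; all NA for an all-zero
#'   profile.
#' @export
mse_scores <- function(means) {
  if (any(means < 0)) stop("negative expression means")
  tot <- sum(means)
  if (tot == 0) return(rep(NA_real_, length(means)))
  p <- means / tot
  e <- -p * log2(p)
  e[p == 0] <- 0
  e / MSE_NORM
}

#' Select transcription factors by annotation identifiers
#'
#' Returns the genes whose annotation identifier set intersects a list of
#' identifiers associated with transcription-factor activity or
#' DNA-binding domains (GO/InterPro/PFam/PANTHER accessions).
#' Intersection with an expressed-gene set is left to the caller.
#'
#' @param annotations named list mapping gene id to a character vector of
#'   identifiers, or a data.frame with columns `gene` and `identifiers`
#'   (semicolon-separated).
#' @param tf_identifiers character vector of TF-associated identifiers.
#' @return Character vector of selected gene ids (possibly empty).
#' @export
select_tfs <- function(annotations, tf_identifiers) {
  if (is.data.frame(annotations)) {
    ids <- strsplit(annotations$identifiers, ";", fixed = TRUE)
    annotations <- stats::setNames(lapply(ids, trimws), annotations$gene)
  }
  if (length(tf_identifiers) == 0L) return(character())
  hit <- vapply(annotations, function(x) any(x %in% tf_identifiers),
                logical(1))
  names(annotations)[hit]
}
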