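#' Tree-ensemble regulator importance matrix
#'
#' GENIE3-style scoring: for every target gene a random-forest regression
#' (via \pkg{ranger}) predicts its expression across samples from all
#' candidate regulator expressions (the target itself excluded), and each
#' regulator's importance is its total impurity (variance) reduction,
#' normalized per target to sum to 1 over regulators. Targets with zero
#' variance get an all-zero column.
#'
#' @param expr an [expression_set] with at least 4 samples.
#' @param regulators character vector of candidate regulator gene ids
#'   (subset of the expression genes).
#' @param ensemble_size trees per target forest (default 500).
#' @param seed integer seed; forests are grown with per-target seeds
#'   derived from it, so the matrix is deterministic.
#' @param targets optional subset of genes to score as targets; defaults
#'   to all genes.
#' @return Numeric matrix, regulators x targets, non-negative, per-target
#'   columns summing to 1 (or 0 for degenerate targets). Self entries are
#'   zero.
#' @export
tree_importance_matrix <- function(expr, regulators, ensemble_size = 500,
                                   seed = 1, targets = NULL) {
  if (!inherits(expr, "expr_set")) stop("'expr' must be an expr_set")
  if (!all(regulators %in% rownames(expr$values)))
    stop("all regulators must be present in the expression matrix")
  if (ncol(expr$values) < 4L) stop("at least 4 samples required")
  if (length(regulators) < 1L) stop("at least one regulator required")
  targets <- targets %||% rownames(expr$values)
  x <- t(expr$values[regulators, , drop = FALSE])
  imp <- matrix(0, nrow = length(regulators), ncol = length(targets),
                dimnames = list(regulators, targets))
  for (k in seq_along(targets)) {
    g <- targets[k]
    y <- expr$values[g, ]
    if (sd(y) == 0) next
    preds <- setdiff(regulators, g)
    if (length(preds) == 0L) next
    if (length(preds) == 1L) {
      # a single candidate gets all the (normalized) importance
      imp[preds, k] <- 1
      next
    }
    dat <- data.frame(x[, preds, drop = FALSE], ..y.. = y,
                      check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "..y..", data = dat,
      num.trees = ensemble_size, importance = "impurity",
      num.threads = 1L,
      seed = (as.integer(seed) + 7919L * k) %% 2147483647L)
    vi <- pmax(fit$variable.importance, 0)
    if (sum(vi) > 0) imp[names(vi), k] <- vi / sum(vi)
  }
  imp
}

#' Threshold an importance matrix into candidate edges
#'
#' Retains the (regulator, target) pairs whose importance reaches the
#' upper `top_fraction` of all non-self importances. The cut point is the
#' order statistic at position ceiling((1 - top_fraction) * n) of the
#' sorted values, and ties at the cut are all retained; zero-importance
#' pairs are never retained.
#'
#' @param imp importance matrix from [tree_importance_matrix()].
#' @param top_fraction fraction of pairs to keep, in (0, 1].
#' @return data.frame of edges (`source`, `target`, `weight`).
#' @export
threshold_edges <- function(imp, top_fraction = 0.02) {
  if (length(imp) == 0L) stop("empty importance matrix")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]")
  regs <- rownames(imp)
  tgts <- colnames(imp)
  src <- rep(regs, times = length(tgts))
  tgt <- rep(tgts, each = length(regs))
  off <- src != tgt
  src <- src[off]
  tgt <- tgt[off]
  w <- as.vector(imp)[off]
  n <- length(w)
  k <- ceiling((1 - top_fraction) * n)
  cut <- if (k < 1L) -Inf else sort(w)[k]
  keep <- w >= cut & w > 0
  data.frame(source = src[keep], target = tgt[keep], weight = w[keep],
             stringsAsFactors = FALSE)
}

#' Consensus edges over inference iterations
#'
#' Keeps edges appearing in at least `min_support` of the per-iteration
#' edge sets; the retained edge's weight is its mean weight over the
#' iterations that proposed it.
#'
#' @param edge_sets list of edge data.frames (`source`, `target`,
#'   optionally `weight`).
#' @param min_support minimum number of supporting sets; defaults to a
#'   majority, ceiling(k/2).
#' @return data.frame of edges with `support` counts.
#' @export
consensus_edges <- function(edge_sets, min_support = NULL) {
  k <- length(edge_sets)
  if (k == 0L) stop("'edge_sets' is empty")
  min_support <- min_support %||% ceiling(k / 2)
  if (min_support < 1 || min_support > k)
    stop("'min_support' must be in [1, number of edge sets]")
  all <- do.call(rbind, lapply(edge_sets, function(e) {
    if (is.null(e$weight)) e$weight <- 1
    e[, c("source", "target", "weight")]
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), support = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(all$source, all$target, sep = "\r")
  support <- table(key)
  keep_keys <- names(support)[support >= min_support]
  if (length(keep_keys) == 0L)
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), support = integer(),
                      stringsAsFactors = FALSE))
  w <- tapply(all$weight, key, mean)[keep_keys]
  parts <- strsplit(keep_keys, "\r", fixed = TRUE)
  data.frame(source = vapply(parts, `[`, "", 1),
             target = vapply(parts, `[`, "", 2),
             weight = as.numeric(w),
             support = as.integer(support[keep_keys]),
             stringsAsFactors = FALSE)
}

#' Assign regulatory signs from time-point means
#'
#' Labels each edge by the Pearson correlation r between the source and
#' target per-time-point mean profiles: `promoting` if r > tau,
#' `repressing` if r < -tau, otherwise `regulating`. Zero-variance
#' profiles give `regulating`.
#'
#' @param edges data.frame of edges (`source`, `target`, optionally
#'   `weight`, `support`).
#' @param means genes x time-points matrix of per-time-point means (see
#'   [time_course_means()]); every edge endpoint must have a row.
#' @param tau dead-zone half-width on the correlation (default 0.3).
#' @param nodes,provenance passed to [grn()].
#' @return A signed [grn].
#' @export
assign_signs <- function(edges, means, tau = 0.3, nodes = NULL,
                         provenance = list()) {
  need <- unique(c(edges$source, edges$target))
  if (!all(need %in% rownames(means)))
    stop("missing time-course profile for: ",
         paste(setdiff(need, rownames(means)), collapse = ", "))
  if (ncol(means) < 3L)
    warning("fewer than 3 time points; correlations are unstable")
  sign <- rep("regulating", nrow(edges))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      xs <- means[edges$source[i], ]
      xt <- means[edges$target[i], ]
      if (sd(xs) == 0 || sd(xt) == 0) next
      r <- cor(xs, xt)
      if (r > tau) sign[i] <- "promoting"
      else if (r < -tau) sign[i] <- "repressing"
    }
  }
  edges$sign <- sign
  grn(edges, nodes = nodes, provenance = provenance)
}

#' Infer a signed network by iterated tree-ensemble ranking
#'
#' The full tree-based engine: `iterations` independent random-forest
#' importance matrices (iteration-specific seeds), each thresholded to
#' its top importance fraction, a majority-vote consensus over
#' iterations, and sign assignment from per-time-point mean profiles.
#' Five iterations is the default for moderate gene sets; use
#' `iterations = 1` for large ones (absent an upstream clustering step
#' the iteration count mainly trades compute for edge-support
#' information).
#'
#' @param expr an [expression_set].
#' @param regulators candidate regulator genes (for an unrestricted run
#'   pass all genes).
#' @param iterations number of independent forest iterations (default 5).
#' @param ensemble_size trees per forest (default 500).
#' @param top_fraction per-iteration importance cutoff (default 0.02).
#' @param tau sign dead-zone (default 0.3).
#' @param min_support consensus support; default majority of iterations.
#' @param seed integer seed.
#' @return A [grn] with provenance recording all parameters.
#' @export
infer_rtp_star <- function(expr, regulators, iterations = 5,
                           ensemble_size = 500, top_fraction = 0.02,
                           tau = 0.3, min_support = NULL, seed = 1) {
  if (iterations < 1) stop("'iterations' must be positive")
  sets <- lapply(seq_len(iterations), function(i) {
    imp <- tree_importance_matrix(expr, regulators,
                                  ensemble_size = ensemble_size,
                                  seed = (as.integer(seed) +
                                            104729L * (i - 1L)) %% 2147483647L)
    threshold_edges(imp, top_fraction = top_fraction)
  })
  cons <- consensus_edges(sets, min_support = min_support)
  assign_signs(cons, time_course_means(expr), tau = tau,
               nodes = rownames(expr$values),
               provenance = list(engine = "rtp_star",
                                 iterations = iterations,
                                 ensemble_size = ensemble_size,
                                 top_fraction = top_fraction, tau = tau,
                                 min_support = min_support %||%
                                   ceiling(iterations / 2),
                                 seed = seed))
}
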