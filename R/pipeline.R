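#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Inputs may
#' be in-memory objects ([expression_set], [count_set], annotation list)
#' or file paths understood by the package readers.
#'
#' @param expression an [expression_set], or path to a matrix TSV (then
#'   `expression_meta` must give the metadata path).
#' @param expression_meta metadata path when `expression` is a path.
#' @param counts a [count_set] (required for `gene_set = "enriched_mse"`).
#' @param annotations named list or annotation TSV path (required for
#'   `gene_set = "tf"`).
#' @param tf_identifiers identifiers marking TF activity / DNA binding.
#' @param gene_set which gene set to build: `"enriched_mse"`
#'   (endosperm-enriched then entropy-filtered), `"mse_all"` (entropy
#'   filter over all genes), or `"tf"` (annotated transcription factors).
#' @param engine `"trees"`, `"kboost"` or `"both"`.
#' @param lfc_threshold,fdr_threshold enrichment thresholds (1.5, 0.01).
#' @param mse_threshold entropy outlier threshold (0.30).
#' @param iterations,ensemble_size,top_fraction,tau tree-engine
#'   parameters (see [infer_rtp_star()]).
#' @param n_components,boosting_rounds,shrinkage kboost parameters (see
#'   [infer_kboost()]).
#' @param n_random,z_threshold,swap_factor motif parameters (see
#'   [motif_enrichment()]).
#' @param n_permutations overlap permutations (default 10000).
#' @param directed_overlap match overlap edges respecting direction.
#' @param seed single integer driving all randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, expression_meta = NULL,
                            counts = NULL, annotations = NULL,
                            tf_identifiers = NULL,
                            gene_set = c("enriched_mse", "mse_all", "tf"),
                            engine = c("both", "trees", "kboost"),
                            lfc_threshold = 1.5, fdr_threshold = 0.01,
                            mse_threshold = 0.30,
                            iterations = 5, ensemble_size = 500,
                            top_fraction = 0.02, tau = 0.3,
                            n_components = NULL, boosting_rounds = 3,
                            shrinkage = 0.5,
                            n_random = 1000, z_threshold = 3.0,
                            swap_factor = 10,
                            n_permutations = 10000,
                            directed_overlap = TRUE, seed = 1) {
  gene_set <- match.arg(gene_set)
  engine <- match.arg(engine)
  stopifnot(lfc_threshold >= 0, fdr_threshold > 0, fdr_threshold <= 1,
            mse_threshold > 0, mse_threshold <= 1,
            top_fraction > 0, top_fraction <= 1,
            shrinkage > 0, shrinkage <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.provenance_header <- function(config, extra = character()) {
  c(paste0("seedgrn ", as.character(utils::packageVersion("seedgrn"))),
    paste0("seed: ", config$seed),
    paste0("gene_set: ", config$gene_set, "; engine: ", config$engine),
    extra)
}

#' Run the full inference workflow
#'
#' Builds the configured gene set, infers the network(s), runs motif
#' enrichment and per-gene motif scoring on each, and — when both
#' engines run — the edge-overlap permutation test. All artifacts are
#' written to `out_dir` as TSV with provenance headers, and returned
#' invisibly as a list.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with elements `gene_set`, `networks`,
#'   `enrichment_table` (when computed), `motifs`, `nms`, `overlap`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance_header(config)

  expr <- config$expression
  if (is.character(expr))
    expr <- read_expression_tsv(expr, config$expression_meta)
  if (!inherits(expr, "expr_set")) stop("no usable expression input")
  means <- time_course_means(expr)
  log("expression: %d genes, %d samples", nrow(expr$values),
      ncol(expr$values))

  enr_table <- NULL
  genes <- switch(config$gene_set,
    enriched_mse = {
      if (is.null(config$counts))
        stop("gene_set 'enriched_mse' requires a count_set input")
      enr_table <- differential_enrichment(config$counts)
      enr_table$p_fdr <- bh_adjust(enr_table$p_raw)
      enriched <- classify_enriched(enr_table, config$lfc_threshold,
                                    config$fdr_threshold)
      enr_table$enriched <- enr_table$gene %in% enriched
      log("enrichment: %d of %d genes endosperm-enriched",
          length(enriched), nrow(enr_table))
      kept <- mse_filter(means, config$mse_threshold)
      intersect(intersect(enriched, kept), rownames(expr$values))
    },
    mse_all = mse_filter(means, config$mse_threshold),
    tf = {
      ann <- config$annotations
      if (is.character(ann)) ann <- read_annotations(ann)
      if (is.null(ann) || is.null(config$tf_identifiers))
        stop("gene_set 'tf' requires annotations and tf_identifiers")
      intersect(select_tfs(ann, config$tf_identifiers),
                rownames(expr$values))
    })
  log("gene set (%s): %d genes", config$gene_set, length(genes))
  if (length(genes) < 3L)
    stop("gene set too small for inference (", length(genes), " genes)")
  sub <- expression_set(expr$values[genes, , drop = FALSE],
                        expr$samples$time_dap, expr$samples$replicate,
                        expr$samples$sample_id)
  write_gene_set(genes, file.path(out_dir, "gene_set.txt"))
  if (!is.null(enr_table))
    .write_tsv(enr_table, file.path(out_dir, "enrichment.tsv"), hdr)

  networks <- list()
  if (config$engine %in% c("trees", "both")) {
    networks$trees <- infer_rtp_star(
      sub, regulators = genes, iterations = config$iterations,
      ensemble_size = config$ensemble_size,
      top_fraction = config$top_fraction, tau = config$tau,
      seed = config$seed)
    log("trees engine: %d edges", nrow(networks$trees$edges))
  }
  if (config$engine %in% c("kboost", "both")) {
    networks$kboost <- infer_kboost_grn(
      sub, regulators = genes, n_components = config$n_components,
      boosting_rounds = config$boosting_rounds,
      shrinkage = config$shrinkage)
    log("kboost engine: %d edges", nrow(networks$kboost$edges))
  }

  motifs <- list()
  scores <- list()
  for (nm in names(networks)) {
    net <- networks[[nm]]
    write_grn_tsv(net, file.path(out_dir, paste0("grn_", nm, ".tsv")), hdr)
    write_sif(net, file.path(out_dir, paste0("grn_", nm, ".sif")))
    cen <- motif_census(net, keep_instances = TRUE)
    enr <- motif_enrichment(net, n_random = config$n_random,
                            z_threshold = config$z_threshold,
                            swap_factor = config$swap_factor,
                            seed = config$seed)
    motifs[[nm]] <- enr
    scores[[nm]] <- nms(net, enr, census = cen)
    log("%s motifs: %d connected triples, %d enriched classes", nm,
        sum(cen$counts), sum(enr$enriched))
    .write_tsv(enr, file.path(out_dir, paste0("motifs_", nm, ".tsv")), hdr)
    .write_tsv(cen$instances,
               file.path(out_dir, paste0("motif_instances_", nm, ".tsv")),
               hdr)
    .write_tsv(scores[[nm]], file.path(out_dir, paste0("nms_", nm, ".tsv")),
               hdr)
  }

  overlap <- NULL
  if (length(networks) == 2L) {
    overlap <- overlap_permutation_test(
      networks$trees, networks$kboost, gene_universe = genes,
      n_permutations = config$n_permutations,
      directed = config$directed_overlap, seed = config$seed)
    log("overlap: %d shared edges, p = %.4g", overlap$observed_overlap,
        overlap$p_value)
    rep <- data.frame(observed_overlap = overlap$observed_overlap,
                      overlap_fraction = overlap$overlap_fraction,
                      n_permutations = overlap$n_permutations,
                      perm_mean = overlap$perm_mean,
                      perm_sd = overlap$perm_sd,
                      perm_max = overlap$perm_max,
                      p_value = overlap$p_value)
    .write_tsv(rep, file.path(out_dir, "overlap.tsv"), hdr)
  }
  invisible(list(gene_set = genes, networks = networks,
                 enrichment_table = enr_table, motifs = motifs,
                 nms = scores, overlap = overlap))
}
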