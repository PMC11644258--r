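#' Time-course expression set
#'
#' Container for a gene-by-sample matrix of non-negative, FPKM-like
#' expression values together with the sample design (time point in days
#' after pollination, replicate index). This is the input object for both
#' inference engines and for the entropy filter.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples
#'   in columns.
#' @param time_dap numeric vector of time points (days after pollination),
#'   one per column of `values`.
#' @param replicate integer vector of replicate indices, one per column.
#' @param sample_id optional character vector of sample names; defaults to
#'   `T<time>_R<replicate>`.
#' @return An object of class `expr_set`: a list with elements `values`
#'   (matrix) and `samples` (data.frame with columns `sample_id`,
#'   `time_dap`, `replicate`).
#' @export
expression_set <- function(values, time_dap, replicate, sample_id = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("'values' must have gene rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("expression values must be finite numerics")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(time_dap) != ncol(values) || length(replicate) != ncol(values))
    stop("'time_dap' and 'replicate' must have one entry per sample")
  if (length(unique(time_dap)) < 2L)
    stop("at least 2 distinct time points are required")
  if (anyDuplicated(paste(time_dap, replicate)))
    stop("(time point, replicate) pairs must be unique")
  if (is.null(sample_id))
    sample_id <- sprintf("T%g_R%d", time_dap, as.integer(replicate))
  colnames(values) <- sample_id
  structure(list(
    values = values,
    samples = data.frame(sample_id = sample_id, time_dap = time_dap,
                         replicate = as.integer(replicate),
                         stringsAsFactors = FALSE)
  ), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d time points x %s replicates)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$time_dap)),
              paste(range(table(x$samples$time_dap)), collapse = "-")))
  invisible(x)
}

#' Two-condition count set
#'
#' Raw counts for the endosperm vs whole-seed enrichment contrast, with an
#' optional per-gene ground-truth enrichment flag (set by the simulator).
#'
#' @param counts integer matrix, genes in rows (rownames required).
#' @param group character vector, one of `"endosperm"`/`"whole_seed"` per
#'   column.
#' @param truth optional named logical vector of true enrichment flags.
#' @return An object of class `count_set`.
#' @export
count_set <- function(counts, group, truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("'counts' must have gene rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(group) != ncol(counts))
    stop("'group' must have one entry per sample")
  if (!all(group %in% c("endosperm", "whole_seed")))
    stop("group labels must be 'endosperm' or 'whole_seed'")
  if (!is.null(truth)) {
    truth <- truth[rownames(counts)]
    names(truth) <- rownames(counts)
  }
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s_%d", group, stats::ave(
      seq_along(group), group, FUN = seq_along))
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = colnames(counts), group = group,
                         stringsAsFactors = FALSE),
    truth = truth
  ), class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat(sprintf("count_set: %d genes, %d endosperm + %d whole-seed samples\n",
              nrow(x$counts), sum(x$samples$group == "endosperm"),
              sum(x$samples$group == "whole_seed")))
  invisible(x)
}

#' Ground-truth regulatory network
#'
#' @param genes character vector of gene ids.
#' @param regulators character vector, subset of `genes`.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1), `strength` (> 0).
#' @return An object of class `gt_network`.
#' @export
gt_network <- function(genes, regulators, edges) {
  stopifnot(all(regulators %in% genes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (!all(edges$source %in% regulators))
      stop("edge sources must be regulators")
    if (!all(edges$target %in% genes)) stop("edge targets must be genes")
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges$source, edges$target)))
      stop("duplicate (source, target) pairs")
    if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
    if (any(edges$strength <= 0)) stop("edge strengths must be positive")
  }
  structure(list(genes = genes, regulators = regulators, edges = edges),
            class = "gt_network")
}

#' @export
print.gt_network <- function(x, ...) {
  cat(sprintf("gt_network: %d genes, %d regulators, %d edges (%d repressing)\n",
              length(x$genes), length(x$regulators), nrow(x$edges),
              sum(x$edges$sign == -1)))
  invisible(x)
}

GRN_SIGNS <- c("promoting", "repressing", "regulating")

#' Directed gene regulatory network
#'
#' The common container for inferred networks: a set of directed
#' source-to-target edges, each with a weight and a sign label
#' (`promoting`, `repressing` or `regulating`), over an explicit node set.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `sign`, and optionally `support` (number of inference iterations the
#'   edge appeared in).
#' @param nodes character vector of gene ids; defaults to the edge
#'   endpoints.
#' @param provenance named list recording how the network was produced
#'   (engine, parameters, seed).
#' @return An object of class `grn`.
#' @export
grn <- function(edges, nodes = NULL, provenance = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), sign = character(),
                        support = integer(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("source", "target") %in% names(edges)))
      stop("edges need 'source' and 'target' columns")
    if (is.null(edges$weight)) edges$weight <- 1
    if (is.null(edges$sign)) edges$sign <- "regulating"
    if (is.null(edges$support)) edges$support <- 1L
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges$source, edges$target)))
      stop("duplicate directed edges")
    if (!all(edges$sign %in% GRN_SIGNS))
      stop("edge sign must be one of: ", paste(GRN_SIGNS, collapse = ", "))
  }
  nodes <- nodes %||% sort(unique(c(edges$source, edges$target)))
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("every edge endpoint must be in the node set")
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, provenance = provenance),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  eng <- x$provenance$engine %||% "unknown engine"
  cat(sprintf("grn (%s): %d nodes, %d edges\n", eng, length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(factor(x$edges$sign, levels = GRN_SIGNS))
    cat(sprintf("  signs: %d promoting, %d repressing, %d regulating\n",
                tab[["promoting"]], tab[["repressing"]], tab[["regulating"]]))
  }
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  topology_summary(object)
}

#' Plot a regulatory network
#'
#' Draws the network with igraph (promoting edges in blue, repressing in
#' red, unsigned in grey). Requires the igraph package.
#'
#' @param x a [grn] object.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.grn <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the 'igraph' package")
  g <- igraph::graph_from_data_frame(
    x$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = x$nodes))
  cols <- c(promoting = "steelblue", repressing = "firebrick",
            regulating = "grey50")
  igraph::plot.igraph(g, edge.color = cols[x$edges$sign],
                      edge.arrow.size = 0.3, vertex.size = 5,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

# Internal: edge keys for set operations.
edge_keys <- function(x, directed = TRUE) {
  e <- if (inherits(x, "grn")) x$edges else x
  if (nrow(e) == 0L) return(character())
  if (directed) paste(e$source, e$target, sep = "\r")
  else paste(pmin(e$source, e$target), pmax(e$source, e$target), sep = "\r")
}
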