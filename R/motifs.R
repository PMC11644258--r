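# Directed 3-node (triad) motif machinery. The canonical form of a triad
# is the minimum of its 6-bit adjacency code over all 6 node relabelings;
# exactly 13 weakly connected classes exist. Counting and randomization
# loops are compiled (src/motifs.cpp); everything here is naming,
# validation and statistics.

# Bit layout of the 6-bit code, ordered pairs among nodes (1,2,3):
# (1,2) (1,3) (2,1) (2,3) (3,1) (3,2) -> bits 0..5.
.code_from_adj <- function(adj) {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  sum(vapply(seq_len(6), function(b) {
    if (adj[pairs[b, 1], pairs[b, 2]] != 0) bitwShiftL(1L, b - 1L) else 0L
  }, integer(1)))
}

.adj_from_code <- function(code) {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  adj <- matrix(0L, 3, 3)
  for (b in seq_len(6))
    if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0)
      adj[pairs[b, 1], pairs[b, 2]] <- 1L
  adj
}

# Holland-Leinhardt style MAN label (mutual/asymmetric/null dyad counts
# plus D/U/C/T disambiguation) computed structurally from a canonical
# code, so labels need no hardcoded table.
.triad_label <- function(code) {
  adj <- .adj_from_code(code)
  pair_idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  dyad <- apply(pair_idx, 1, function(p) adj[p[1], p[2]] + adj[p[2], p[1]])
  m <- sum(dyad == 2)
  a <- sum(dyad == 1)
  n <- sum(dyad == 0)
  base <- sprintf("%d%d%d", m, a, n)
  outd <- rowSums(adj)
  ind <- colSums(adj)
  suffix <- ""
  if (base == "021") {
    suffix <- if (any(outd == 2)) "D" else if (any(ind == 2)) "U" else "C"
  } else if (base == "030") {
    suffix <- if (all(outd == 1) && all(ind == 1)) "C" else "T"
  } else if (base %in% c("111", "120")) {
    dy <- pair_idx[dyad == 2, , drop = FALSE][1, ]
    x <- setdiff(1:3, dy)  # the node outside the mutual dyad
    x_out <- sum(adj[x, dy])
    x_in <- sum(adj[dy, x])
    if (base == "111") {
      suffix <- if (x_out == 1) "D" else "U"
    } else {
      suffix <- if (x_out == 2) "D" else if (x_in == 2) "U" else "C"
    }
  }
  paste0(base, suffix)
}

.triad_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- .triad_class_codes_cpp()
      desc <- c("021D" = "divergence (A<-B->C)",
                "021U" = "convergence (A->B<-C)",
                "021C" = "chain (A->B->C)",
                "111D" = "mutual dyad, incoming spoke",
                "111U" = "mutual dyad, outgoing spoke",
                "030T" = "feed-forward loop",
                "030C" = "3-cycle",
                "201" = "two mutual dyads",
                "120D" = "mutual dyad, double source",
                "120U" = "mutual dyad, double sink",
                "120C" = "mutual dyad in a chain",
                "210" = "mutual-rich triad",
                "300" = "fully reciprocal triangle")
      labels <- vapply(codes, .triad_label, "")
      tab <<- data.frame(class = seq_along(codes), label = labels,
                         code = codes,
                         description = unname(desc[labels]),
                         stringsAsFactors = FALSE)
    }
    tab
  }
})

#' The 13 connected directed triad classes
#'
#' @return data.frame with columns `class` (index), `label`
#'   (Holland-Leinhardt MAN label, e.g. `030T` for the feed-forward
#'   loop), `code` (canonical 6-bit adjacency code) and `description`.
#' @export
triad_classes <- function() .triad_table()

#' Canonical class of a 3-node directed subgraph
#'
#' @param adj 3x3 binary adjacency matrix (rows regulate columns), no
#'   self-loops.
#' @return The class label (e.g. `"030T"`), or `NA` if the subgraph is
#'   not weakly connected.
#' @export
canonical_class <- function(adj) {
  adj <- as.matrix(adj)
  if (!all(dim(adj) == c(3, 3))) stop("'adj' must be 3x3")
  if (any(diag(adj) != 0)) stop("self-loops are not allowed")
  cls <- .classify_triad_code_cpp(.code_from_adj(adj))
  if (cls == 0L) NA_character_ else .triad_table()$label[cls]
}

.net_edge_index <- function(net) {
  nodes <- net$nodes
  list(src = match(net$edges$source, nodes) - 1L,
       dst = match(net$edges$target, nodes) - 1L,
       nodes = nodes)
}

#' Census of connected 3-node subgraphs
#'
#' Counts every unordered node triple whose induced subgraph is weakly
#' connected, once, under its isomorphism class. Edge signs are ignored:
#' motif structure is purely topological.
#'
#' @param net a [grn].
#' @param keep_instances record the node triple of every occurrence
#'   (default TRUE).
#' @return A list of class `motif_census`: `counts` (named integer
#'   vector over the 13 class labels) and `instances` (data.frame
#'   `class`, `node_a`, `node_b`, `node_c`; empty when
#'   `keep_instances = FALSE`).
#' @export
motif_census <- function(net, keep_instances = TRUE) {
  if (!inherits(net, "grn")) stop("'net' must be a grn")
  ix <- .net_edge_index(net)
  res <- .census_cpp(ix$src, ix$dst, length(ix$nodes), keep_instances)
  tab <- .triad_table()
  counts <- stats::setNames(res$counts, tab$label)
  inst <- res$instances
  instances <- data.frame(
    class = tab$label[inst[, 4]],
    node_a = ix$nodes[inst[, 1] + 1L],
    node_b = ix$nodes[inst[, 2] + 1L],
    node_c = ix$nodes[inst[, 3] + 1L],
    stringsAsFactors = FALSE)
  structure(list(counts = counts, instances = instances),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("motif_census:", sum(x$counts), "connected triples\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz)
  invisible(x)
}

#' Degree-preserving network randomization
#'
#' Applies `swap_factor * |E|` attempted directed two-edge switches
#' (a->b, c->d) => (a->d, c->b), rejecting any switch that would create
#' a self-loop or duplicate edge. Every node's in- and out-degree is
#' preserved exactly, which is the standard null model for motif
#' detection.
#'
#' @param net a [grn] with at least 2 edges.
#' @param swap_factor attempted switches per edge (default 10).
#' @param seed integer seed.
#' @return A [grn] over the same node set with shuffled edges (weights
#'   and signs are not meaningful and are reset).
#' @export
randomize_network <- function(net, swap_factor = 10, seed = 1) {
  if (!inherits(net, "grn")) stop("'net' must be a grn")
  if (nrow(net$edges) < 2L) return(net)
  ix <- .net_edge_index(net)
  res <- with_seed(seed, .randomize_cpp(ix$src, ix$dst, length(ix$nodes),
                                        as.integer(swap_factor *
                                                     length(ix$src))))
  grn(data.frame(source = ix$nodes[res$src + 1L],
                 target = ix$nodes[res$dst + 1L],
                 weight = 1, sign = "regulating",
                 stringsAsFactors = FALSE),
      nodes = net$nodes,
      provenance = list(engine = "randomized", swap_factor = swap_factor,
                        seed = seed))
}

#' Motif over-representation against randomized networks
#'
#' Compares each triad class count in the network with its distribution
#' over `n_random` randomized networks of the same size (same node and
#' edge counts; degree-preserving switching by default, or an
#' Erdos-Renyi same-n-same-m null). A class is enriched when
#' z = (count - mean_random) / sd_random exceeds `z_threshold`; classes
#' with zero null variance are reported with z = 0 and never enriched.
#'
#' @param net a [grn].
#' @param n_random number of randomized networks (default 1000).
#' @param z_threshold enrichment threshold on the z-score (default 3.0).
#' @param swap_factor switching intensity (see [randomize_network()]).
#' @param seed integer seed.
#' @param null_model `"switching"` (degree-preserving, default) or
#'   `"erdos_renyi"`.
#' @return data.frame with one row per class: `class`, `count_real`,
#'   `mean_random`, `sd_random`, `z_score`, `enriched`.
#' @export
motif_enrichment <- function(net, n_random = 1000, z_threshold = 3.0,
                             swap_factor = 10, seed = 1,
                             null_model = c("switching", "erdos_renyi")) {
  if (!inherits(net, "grn")) stop("'net' must be a grn")
  if (n_random < 2) stop("'n_random' must be at least 2")
  null_model <- match.arg(null_model)
  ix <- .net_edge_index(net)
  real <- .census_cpp(ix$src, ix$dst, length(ix$nodes), FALSE)$counts
  null_counts <- with_seed(seed, .motif_null_counts_cpp(
    ix$src, ix$dst, length(ix$nodes), as.integer(n_random),
    as.integer(swap_factor * length(ix$src)),
    null_model == "erdos_renyi"))
  mu <- colMeans(null_counts)
  sdev <- apply(null_counts, 2, sd)
  z <- ifelse(sdev > 0, (real - mu) / sdev, 0)
  data.frame(class = .triad_table()$label, count_real = real,
             mean_random = mu, sd_random = sdev, z_score = z,
             enriched = z > z_threshold & sdev > 0,
             stringsAsFactors = FALSE)
}

#' Per-gene network motif scores
#'
#' The network motif score (NMS) of a gene is the number of occurrences
#' of enriched motif classes that contain it. Genes appearing in no
#' enriched-motif occurrence are absent from the table (their score is
#' zero); with no enriched class the table is empty.
#'
#' @param net a [grn].
#' @param enrichment output of [motif_enrichment()] for `net`.
#' @param census optional precomputed [motif_census()] with instances,
#'   to avoid recounting.
#' @return data.frame (`gene`, `score`) sorted by decreasing score.
#' @export
nms <- function(net, enrichment, census = NULL) {
  if (!all(c("class", "enriched") %in% names(enrichment)))
    stop("'enrichment' must come from motif_enrichment()")
  census <- census %||% motif_census(net, keep_instances = TRUE)
  good <- enrichment$class[enrichment$enriched]
  inst <- census$instances[census$instances$class %in% good, , drop = FALSE]
  if (nrow(inst) == 0L)
    return(data.frame(gene = character(), score = integer(),
                      stringsAsFactors = FALSE))
  cnt <- table(c(inst$node_a, inst$node_b, inst$node_c))
  out <- data.frame(gene = names(cnt), score = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}
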