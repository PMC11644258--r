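#' Shared edges between two networks
#'
#' @param a,b [grn] objects (or edge data.frames with `source`/`target`).
#' @param directed match edges respecting direction (default TRUE); with
#'   `directed = FALSE` the pairs (s,t) and (t,s) are collapsed.
#' @return Number of (unique) edges of `a` also present in `b`.
#' @export
edge_overlap <- function(a, b, directed = TRUE) {
  length(intersect(unique(edge_keys(a, directed)),
                   unique(edge_keys(b, directed))))
}

#' Permutation test of edge overlap between two networks
#'
#' Tests whether two networks inferred on a common gene set share more
#' edges than expected by chance. Each permutation draws `|E_A|` random
#' gene pairs from the universe — two distinct genes per pair, sampled
#' without replacement, with no duplicate pairs within a permutation —
#' and counts how many fall in network `b`. The empirical p-value uses
#' add-one smoothing, p = (1 + #\{permuted >= observed\}) / (1 + n),
#' so it is never exactly zero and its minimum at 10,000 permutations is
#' just under 1e-4.
#'
#' @param a,b [grn] objects; `a` supplies the pair count.
#' @param gene_universe the common gene set used for inference (>= 3
#'   genes; must contain every edge endpoint of `a` and `b`).
#' @param n_permutations number of random pairings (default 10000).
#' @param directed match and draw ordered pairs (default TRUE).
#' @param seed integer seed.
#' @return An object of class `overlap_test`: list with
#'   `observed_overlap`, `overlap_fraction` (observed / |E_A|),
#'   `n_permutations`, `permuted` (the null draws), `perm_mean`,
#'   `perm_sd`, `perm_max`, `p_value`, and `p_randomized` (the uniform
#'   tie-broken p-value; because the overlap count is discrete the
#'   add-one p takes few distinct values, and the randomized version is
#'   the quantity that is exactly uniform under the null, useful for
#'   calibration checks).
#' @export
overlap_permutation_test <- function(a, b, gene_universe,
                                     n_permutations = 10000,
                                     directed = TRUE, seed = 1) {
  u <- unique(gene_universe)
  if (length(u) < 3L) stop("gene universe must contain at least 3 genes")
  ends <- unique(c(a$edges$source, a$edges$target,
                   b$edges$source, b$edges$target))
  if (!all(ends %in% u))
    stop("edge endpoints outside the gene universe: ",
         paste(utils::head(setdiff(ends, u), 5), collapse = ", "))
  if (n_permutations < 1) stop("'n_permutations' must be positive")
  nu <- length(u)
  n_pairs <- if (directed) nu * (nu - 1) else nu * (nu - 1) / 2
  akeys <- unique(edge_keys(a, directed))
  m <- length(akeys)
  if (m > n_pairs)
    stop("network 'a' has more edges than there are distinct gene pairs")
  observed <- edge_overlap(a, b, directed)
  # integer-coded edge set of b for fast membership tests
  bi <- b$edges
  bs <- match(bi$source, u)
  bt <- match(bi$target, u)
  bkeys <- if (directed) (bs - 1) * nu + bt
           else (pmin(bs, bt) - 1) * nu + pmax(bs, bt)
  bkeys <- unique(bkeys)
  draw <- if (m == 0L) list(perm = rep(0L, n_permutations), u = 0.5)
  else with_seed(seed, {
    out <- vapply(seq_len(n_permutations), function(p) {
      idx <- sample(n_pairs, m)  # distinct pairs within the permutation
      if (directed) {
        i <- (idx - 1) %/% (nu - 1) + 1
        r <- (idx - 1) %% (nu - 1) + 1
        j <- r + (r >= i)
      } else {
        # enumerate unordered pairs (i < j) row by row
        i <- findInterval(idx - 1, cumsum(c(0, (nu - 1):1)),
                          rightmost.closed = FALSE)
        off <- idx - (cumsum(c(0, (nu - 1):1)))[i]
        j <- i + off
      }
      keys <- if (directed) (i - 1) * nu + j
              else (pmin(i, j) - 1) * nu + pmax(i, j)
      sum(keys %in% bkeys)
    }, integer(1))
    list(perm = out, u = runif(1))
  })
  permuted <- draw$perm
  p <- (1 + sum(permuted >= observed)) / (1 + n_permutations)
  p_rand <- (sum(permuted > observed) +
               draw$u * (1 + sum(permuted == observed))) /
    (1 + n_permutations)
  structure(list(observed_overlap = observed,
                 overlap_fraction = if (m > 0) observed / m else 0,
                 n_permutations = n_permutations,
                 permuted = permuted,
                 perm_mean = mean(permuted),
                 perm_sd = sd(permuted),
                 perm_max = max(permuted),
                 p_value = p,
                 p_randomized = p_rand),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: observed %d shared edges (fraction %.3f of network A)\n",
    x$observed_overlap, x$overlap_fraction))
  cat(sprintf("  null (n = %d): mean %.2f, sd %.2f, max %d\n",
              x$n_permutations, x$perm_mean, x$perm_sd, x$perm_max))
  cat(sprintf("  empirical p-value = %.4g\n", x$p_value))
  invisible(x)
}

#' Topology summary of a network
#'
#' @param net a [grn].
#' @return A list of class `topology_summary`: `n_nodes`, `n_edges`,
#'   `mean_in_degree`, `max_in_degree`, `mean_out_degree`,
#'   `max_out_degree`, and `in_degree_hist` (a table over the node set,
#'   so it sums to the node count).
#' @export
topology_summary <- function(net) {
  if (!inherits(net, "grn")) stop("'net' must be a grn")
  nodes <- net$nodes
  ind <- table(factor(net$edges$target, levels = nodes))
  outd <- table(factor(net$edges$source, levels = nodes))
  structure(list(
    n_nodes = length(nodes),
    n_edges = nrow(net$edges),
    mean_in_degree = mean(ind),
    max_in_degree = if (length(ind)) max(ind) else 0,
    mean_out_degree = mean(outd),
    max_out_degree = if (length(outd)) max(outd) else 0,
    in_degree_hist = table(as.integer(ind))
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("topology: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  in-degree  mean %.3f, max %d\n", x$mean_in_degree,
              x$max_in_degree))
  cat(sprintf("  out-degree mean %.3f, max %d\n", x$mean_out_degree,
              x$max_out_degree))
  invisible(x)
}
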