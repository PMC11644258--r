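# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (all-triples enumeration, explicit step-up loops) so
# it can serve as a reference against the package's optimized paths.

# deterministic random directed network, no self-loops, no duplicates
random_test_grn <- function(n_nodes, m, seed, prefix = "n") {
  set.seed(seed)
  nodes <- sprintf("%s%03d", prefix, seq_len(n_nodes))
  pairs <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
  pairs <- pairs[pairs$s != pairs$t, ]
  idx <- sample(nrow(pairs), m)
  grn(data.frame(source = nodes[pairs$s[idx]], target = nodes[pairs$t[idx]],
                 weight = 1, sign = "regulating", stringsAsFactors = FALSE),
      nodes = nodes)
}

# k vertex-disjoint feed-forward loops A->B, A->C, B->C
planted_ffl_grn <- function(k) {
  e <- do.call(rbind, lapply(seq_len(k), function(i) {
    a <- sprintf("A%03d", i)
    b <- sprintf("B%03d", i)
    cc <- sprintf("C%03d", i)
    data.frame(source = c(a, a, b), target = c(b, cc, cc),
               stringsAsFactors = FALSE)
  }))
  grn(cbind(e, weight = 1, sign = "regulating"))
}

# --- independent triad oracle (pure R, all-triples) -------------------

# 6-bit code of a 3x3 adjacency, pair order (1,2)(1,3)(2,1)(2,3)(3,1)(3,2)
oracle_triad_code <- function(adj) {
  pr <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  code <- 0L
  for (b in 1:6)
    if (adj[pr[b, 1], pr[b, 2]] != 0) code <- code + 2L^(b - 1L)
  code
}

oracle_canon_code <- function(adj) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  min(vapply(perms, function(p) oracle_triad_code(adj[p, p]), numeric(1)))
}

# weak connectivity by boolean reachability on the skeleton
oracle_connected3 <- function(adj) {
  sk <- (adj + t(adj)) > 0
  reach <- sk | diag(TRUE, 3)
  for (i in 1:2) reach <- reach | (reach %*% reach > 0)
  all(reach)
}

# census by canonical code over every node triple
oracle_census <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges))
    adj[cbind(net$edges$source, net$edges$target)] <- 1L
  counts <- integer()
  if (n < 3) return(counts)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- adj[c(i, j, k), c(i, j, k)]
    if (!oracle_connected3(a)) next
    code <- as.character(oracle_canon_code(a))
    counts[code] <- (if (is.na(counts[code])) 0L else counts[code]) + 1L
  }
  counts
}

# compare a package census against the oracle, matching classes by
# canonical code
expect_census_matches_oracle <- function(net) {
  got <- motif_census(net, keep_instances = FALSE)$counts
  want <- oracle_census(net)
  key <- as.character(triad_classes()$code)
  full <- stats::setNames(integer(13), key)
  full[names(want)] <- want
  expect_equal(unname(got), unname(full[key]))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# expression set with arbitrary sample layout from a value matrix
make_expr <- function(values) {
  n <- ncol(values)
  expression_set(values, time_dap = rep(seq_len(ceiling(n / 2)),
                                        each = 2)[seq_len(n)],
                 replicate = rep(1:2, length.out = n))
}
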