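adj3 <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  a <- matrix(0, 3, 3)
  a[e] <- 1
  a
}

test_that("isomorphic triads share a class and distinct ones do not", {
  path1 <- adj3(1, 2, 2, 3)       # A->B->C
  path2 <- adj3(3, 2, 2, 1)       # C->B->A
  expect_equal(canonical_class(path1), canonical_class(path2))
  ffl <- adj3(1, 2, 1, 3, 2, 3)
  cyc <- adj3(1, 2, 2, 3, 3, 1)
  expect_equal(canonical_class(ffl), "030T")
  expect_equal(canonical_class(cyc), "030C")
  expect_false(canonical_class(ffl) == canonical_class(cyc))
  expect_true(is.na(canonical_class(adj3(1, 2))))  # disconnected
  loop <- diag(3)
  expect_error(canonical_class(loop), "self-loops")
})

test_that("exhaustive enumeration of the 64 triads yields 13 connected
           classes", {
  labels <- character()
  codes <- numeric()
  for (code in 0:63) {
    a <- matrix(0, 3, 3)
    bit <- 1
    for (p in list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))) {
      if (bitwAnd(code, bit)) a[p[1], p[2]] <- 1
      bit <- bit * 2
    }
    cl <- canonical_class(a)
    if (!is.na(cl)) {
      labels <- c(labels, cl)
      codes <- c(codes, oracle_canon_code(a))
    }
  }
  expect_equal(length(unique(labels)), 13)
  expect_equal(length(unique(codes)), 13)
  # package canonical codes coincide with the oracle's
  expect_setequal(unique(codes), triad_classes()$code)
})

test_that("the census counts each connected triple exactly once", {
  ffl_net <- grn(data.frame(source = c("A", "A", "B"),
                            target = c("B", "C", "C"),
                            weight = 1, sign = "regulating"))
  cen <- motif_census(ffl_net)
  expect_equal(sum(cen$counts), 1)
  expect_equal(unname(cen$counts["030T"]), 1)
  expect_equal(nrow(cen$instances), 1)
  expect_setequal(unlist(cen$instances[1, 2:4]), c("A", "B", "C"))
  empty <- grn(data.frame(), nodes = c("A", "B", "C"))
  expect_true(all(motif_census(empty)$counts == 0))
})

test_that("census counts equal the all-triples oracle and igraph", {
  for (trial in 1:6) {
    net <- random_test_grn(12, 25, seed = trial)
    expect_census_matches_oracle(net)
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = TRUE,
                                       vertices = net$nodes)
    tc <- igraph::triad_census(g)
    names(tc) <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
    mine <- motif_census(net, keep_instances = FALSE)$counts
    expect_equal(unname(mine), unname(tc[names(mine)]))
  }
})

test_that("switching randomization preserves both degree sequences", {
  net <- random_test_grn(40, 120, seed = 2)
  degs <- function(x) list(
    i = table(factor(x$edges$target, levels = x$nodes)),
    o = table(factor(x$edges$source, levels = x$nodes)))
  d0 <- degs(net)
  for (seed in 1:10) {
    r <- randomize_network(net, swap_factor = 10, seed = seed)
    d <- degs(r)
    expect_equal(d$i, d0$i)
    expect_equal(d$o, d0$o)
    expect_equal(nrow(r$edges), nrow(net$edges))
    expect_false(any(r$edges$source == r$edges$target))
  }
  # a two-edge network with no admissible swap is returned unchanged
  stuck <- grn(data.frame(source = c("A", "A"), target = c("B", "C"),
                          weight = 1, sign = "regulating"))
  r <- randomize_network(stuck, 10, seed = 1)
  expect_setequal(paste(r$edges$source, r$edges$target), c("A B", "A C"))
})

test_that("switching mixes the edge set thoroughly", {
  net <- random_test_grn(60, 200, seed = 99)
  jac <- vapply(1:20, function(seed) {
    r <- randomize_network(net, swap_factor = 10, seed = seed)
    a <- paste(net$edges$source, net$edges$target)
    b <- paste(r$edges$source, r$edges$target)
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  expect_lt(median(jac), 0.5)
})

test_that("planted feed-forward loops are called enriched and absent
           classes are not", {
  net <- planted_ffl_grn(50)
  enr <- motif_enrichment(net, n_random = 200, seed = 4)
  expect_true(enr$enriched[enr$class == "030T"])
  expect_gt(enr$z_score[enr$class == "030T"], 3)
  # classes absent from data and null get z = 0, not enriched
  absent <- enr[enr$class == "300", ]
  expect_equal(absent$z_score, 0)
  expect_false(absent$enriched)
  expect_error(motif_enrichment(net, n_random = 1), "at least 2")
})

test_that("strong enrichment calls survive node relabeling", {
  set.seed(42)
  net <- planted_ffl_grn(30)
  perm_nodes <- sprintf("X%03d", seq_along(net$nodes))
  map <- stats::setNames(sample(perm_nodes), net$nodes)
  net2 <- grn(data.frame(source = unname(map[net$edges$source]),
                         target = unname(map[net$edges$target]),
                         weight = 1, sign = "regulating"),
              nodes = unname(map[net$nodes]))
  e1 <- motif_enrichment(net, n_random = 300, seed = 5)
  e2 <- motif_enrichment(net2, n_random = 300, seed = 6)
  expect_equal(e1$count_real, e2$count_real)
  expect_equal(e1$enriched, e2$enriched)
})

test_that("network motif scores count enriched instances per gene", {
  net <- grn(data.frame(source = c("A", "A", "B", "A", "A", "D"),
                        target = c("B", "C", "C", "D", "E", "E"),
                        weight = 1, sign = "regulating"))
  enr <- motif_enrichment(net, n_random = 50, seed = 1)
  enr$enriched <- enr$class == "030T"  # force: scoring logic under test
  sc <- nms(net, enr)
  got <- stats::setNames(sc$score, sc$gene)
  expect_equal(got[["A"]], 2)  # A sits in both FFLs
  expect_equal(got[["B"]], 1)
  expect_equal(got[["E"]], 1)
  enr$enriched <- rep(FALSE, nrow(enr))
  expect_equal(nrow(nms(net, enr)), 0)
})
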