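test_that("a lone candidate regulator takes all the importance", {
  set.seed(1)
  v <- matrix(abs(rnorm(3 * 12, 3)), nrow = 3,
              dimnames = list(c("R", "T1", "T2"), NULL))
  expr <- make_expr(v)
  imp <- tree_importance_matrix(expr, regulators = "R", seed = 1)
  expect_equal(imp["R", "T1"], 1)
  expect_equal(imp["R", "T2"], 1)
  expect_equal(imp["R", "R"], 0)  # no self-regulation
})

test_that("a constant target yields an all-zero importance column", {
  set.seed(2)
  v <- rbind(matrix(abs(rnorm(3 * 12, 3)), nrow = 3), FLAT = rep(2, 12))
  rownames(v)[1:3] <- c("R1", "R2", "R3")
  expr <- make_expr(v)
  imp <- tree_importance_matrix(expr, regulators = c("R1", "R2", "R3"),
                                seed = 2)
  expect_true(all(imp[, "FLAT"] == 0))
})

test_that("the driving regulator dominates an independent one, agreeing
           with a reference forest", {
  set.seed(7)
  n <- 60
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = 0.1)
  v <- rbind(X1 = x1 - min(x1), X2 = x2 - min(x2), Y = y - min(y))
  expr <- make_expr(v)
  imp <- tree_importance_matrix(expr, c("X1", "X2"), ensemble_size = 500,
                                seed = 7)
  expect_gt(imp["X1", "Y"], 3 * imp["X2", "Y"])
  # reference tree ensemble attributes the same dominance
  rf <- randomForest::randomForest(data.frame(X1 = x1, X2 = x2), y,
                                   ntree = 500)
  ri <- randomForest::importance(rf)[, 1]
  expect_gt(ri["X1"], 3 * ri["X2"])
})

test_that("importance thresholding keeps the documented top fraction", {
  set.seed(3)
  imp <- matrix(sample(seq(0.001, 0.9, length.out = 100)), 10, 10,
                dimnames = list(sprintf("r%02d", 1:10),
                                sprintf("r%02d", 1:10)))
  diag(imp) <- 0
  got <- threshold_edges(imp, top_fraction = 0.1)
  off <- imp[row(imp) != col(imp)]
  expect_equal(nrow(got), 10)
  expect_setequal(got$weight, sort(off, decreasing = TRUE)[1:10])
  # degenerate all-equal matrix: ties at the cut retain everything
  eq <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  expect_equal(nrow(threshold_edges(eq, 0.25)), 12)
  # top_fraction 1 keeps every non-zero pair
  expect_equal(nrow(threshold_edges(imp, 1)), 90)
  expect_error(threshold_edges(matrix(numeric(), 0, 0)), "empty")
})

test_that("consensus counts supports exactly like a brute-force filter", {
  e <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2], weight = 1)
  }
  sets <- list(e("a", "b", "b", "c"), e("a", "b"), e("a", "b", "c", "d"),
               e("b", "c"), e("c", "d"))
  got <- consensus_edges(sets, min_support = 3)
  expect_setequal(paste(got$source, got$target), "a b")
  expect_equal(got$support, 3L)
  # present in 2 of 5 is dropped at majority support
  expect_false("b c" %in% paste(got$source, got$target))
  # k = 1 with support 1 is the identity
  one <- consensus_edges(sets[1], min_support = 1)
  expect_setequal(paste(one$source, one$target), c("a b", "b c"))
  expect_error(consensus_edges(list()), "empty")
  # randomized brute-force comparison + monotonicity in support
  set.seed(8)
  for (trial in 1:10) {
    sets <- lapply(1:5, function(i) {
      k <- sample(3:12, 1)
      s <- sample(letters[1:6], k, TRUE)
      t <- sample(LETTERS[1:6], k, TRUE)
      unique(data.frame(source = s, target = t, weight = 1))
    })
    keys <- unlist(lapply(sets, function(x) paste(x$source, x$target)))
    for (ms in 1:5) {
      got <- consensus_edges(sets, min_support = ms)
      want <- names(table(keys))[table(keys) >= ms]
      expect_setequal(paste(got$source, got$target), want)
    }
    key_of <- function(df) {
      if (nrow(df)) paste(df$source, df$target) else character(0)
    }
    expect_true(all(key_of(consensus_edges(sets, 5)) %in%
                      key_of(consensus_edges(sets, 3))))
  }
})

test_that("sign assignment follows the correlation dead-zone rule", {
  means <- rbind(src = 1:6, up = seq(2, 12, 2), down = seq(12, 2, -2),
                 flat = rep(3, 6))
  edges <- data.frame(source = "src", target = c("up", "down", "flat"),
                      weight = 1)
  net <- assign_signs(edges, means)
  got <- stats::setNames(net$edges$sign, net$edges$target)
  expect_equal(got[["up"]], "promoting")
  expect_equal(got[["down"]], "repressing")
  expect_equal(got[["flat"]], "regulating")
  expect_error(assign_signs(data.frame(source = "src", target = "ghost",
                                       weight = 1), means), "missing")
})

test_that("sign labels are antisymmetric under target reflection", {
  set.seed(11)
  for (i in 1:20) {
    means <- rbind(s = abs(rnorm(6, 3)), t = abs(rnorm(6, 3)))
    refl <- means
    refl["t", ] <- 2 * mean(refl["t", ]) - refl["t", ]
    e <- data.frame(source = "s", target = "t", weight = 1)
    a <- assign_signs(e, means)$edges$sign
    b <- assign_signs(e, refl)$edges$sign
    flip <- c(promoting = "repressing", repressing = "promoting",
              regulating = "regulating")
    expect_equal(b, unname(flip[a]))
  }
})

test_that("the iterated tree engine recovers a clean single edge and is
           deterministic", {
  net <- gt_network(sprintf("G%02d", 1:10), "G01",
                    data.frame(source = "G01", target = "G02", sign = 1,
                               strength = 1.5))
  expr <- simulate_time_course(net, noise_sd = 0, seed = 3)
  g1 <- infer_rtp_star(expr, regulators = rownames(expr$values),
                       iterations = 3, ensemble_size = 200, seed = 3)
  expect_true(any(g1$edges$source == "G01" & g1$edges$target == "G02"))
  g2 <- infer_rtp_star(expr, regulators = rownames(expr$values),
                       iterations = 3, ensemble_size = 200, seed = 3)
  expect_identical(g1$edges, g2$edges)
  expect_equal(g1$provenance$engine, "rtp_star")
})
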