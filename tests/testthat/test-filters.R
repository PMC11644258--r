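test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)))
})

test_that("BH adjustment agrees with a brute-force step-up oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p))
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
    # order invariance
    o <- sample(seq_along(p))
    expect_equal(bh_adjust(p[o]), got[o])
  }
})

test_that("log2 fold changes are zero for duplicated samples and are
           library-size invariant", {
  set.seed(1)
  m <- matrix(rpois(200 * 4, 50), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  dup <- count_set(cbind(m, m), rep(c("endosperm", "whole_seed"), each = 4))
  rec <- differential_enrichment(dup)
  expect_true(all(abs(rec$log2fc) < 1e-12))
  # scaling one sample's library leaves every log2fc unchanged
  cs1 <- simulate_two_condition_counts(300, 30, 2, 0.1, 4, seed = 3)
  scaled <- cs1$counts
  scaled[, 1] <- scaled[, 1] * 10L
  cs2 <- count_set(scaled, cs1$samples$group)
  expect_equal(differential_enrichment(cs1)$log2fc,
               differential_enrichment(cs2)$log2fc)
})

test_that("a group with fewer than 2 samples is rejected", {
  m <- matrix(rpois(50 * 3, 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  cs <- count_set(m, c("endosperm", "whole_seed", "whole_seed"))
  expect_error(differential_enrichment(cs), "at least 2 samples")
})

test_that("estimated fold changes recover the planted effect up to the
           library-size composition shift", {
  cs <- simulate_two_condition_counts(2000, 200, 2, 0.1, 7, seed = 5)
  rec <- differential_enrichment(cs)
  # enriched genes inflate the endosperm library, so the CPM fold change
  # of a planted 2^2 effect is attenuated by the library-size ratio
  endo <- cs$samples$group == "endosperm"
  lib_ratio <- mean(colSums(cs$counts[, endo])) /
    mean(colSums(cs$counts[, !endo]))
  want <- 2 - log2(lib_ratio)
  expect_equal(median(rec$log2fc[cs$truth[rec$gene]]), want,
               tolerance = 0.1)
  expect_equal(median(rec$log2fc[!cs$truth[rec$gene]]), -log2(lib_ratio),
               tolerance = 0.1)
})

test_that("end-to-end enrichment recovery clears the frozen floors", {
  cs <- simulate_two_condition_counts(2000, 200, 2, 0.1, 7, seed = 5)
  rec <- differential_enrichment(cs)
  rec$p_fdr <- bh_adjust(rec$p_raw)
  sel <- classify_enriched(rec)
  sens <- mean(names(cs$truth)[cs$truth] %in% sel)
  spc <- 1 - mean(names(cs$truth)[!cs$truth] %in% sel)
  # the strict log2FC > 1.5 cut sits close to the composition-attenuated
  # median effect (~1.6), so sensitivity plateaus near 0.6 while the
  # false-positive rate is essentially zero
  expect_gte(sens, 0.55)
  expect_gte(spc, 0.99)
})

test_that("enrichment classification applies the strict 1.5 / 0.01 rule", {
  rec <- data.frame(gene = c("haiku1_like", "titan_like", "below_lfc",
                             "boundary"),
                    log2fc = c(1.61, 2.87, 1.4, 1.5),
                    p_raw = c(1e-5, 1e-7, 1e-4, 1e-4),
                    p_fdr = c(4.55e-4, 2.90e-6, 0.001, 0.001))
  got <- classify_enriched(rec)
  expect_true(all(c("haiku1_like", "titan_like") %in% got))
  expect_false("below_lfc" %in% got)
  expect_false("boundary" %in% got)   # strict inequality
  rec$p_fdr <- NA_real_
  expect_error(classify_enriched(rec), "p_fdr")
})

test_that("classification is monotone in both thresholds", {
  set.seed(9)
  rec <- data.frame(gene = sprintf("g%03d", 1:300),
                    log2fc = rnorm(300, 1, 1.5),
                    p_raw = runif(300))
  rec$p_fdr <- bh_adjust(rec$p_raw)
  base <- classify_enriched(rec, 1.0, 0.05)
  expect_true(all(classify_enriched(rec, 1.5, 0.05) %in% base))
  expect_true(all(classify_enriched(rec, 1.0, 0.01) %in% base))
})

test_that("entropy filter keeps spikes, drops flat profiles, and is
           scale invariant", {
  prof <- rbind(uniform = rep(5, 6),
                spike = c(0, 0, 0, 0, 0, 10),
                zero = rep(0, 6))
  kept <- mse_filter(prof)
  expect_identical(kept, "spike")
  # worked per-value scores
  s_unif <- mse_scores(rep(5, 6))
  expect_equal(s_unif, rep(0.8117, 6), tolerance = 1e-3)
  expect_equal(mse_scores(c(0, 0, 0, 0, 0, 10)), rep(0, 6))
  expect_true(all(is.na(mse_scores(rep(0, 4)))))
  expect_error(mse_filter(rbind(a = c(-1, 2))), "negative")
  # scale invariance over random profiles
  set.seed(5)
  prof2 <- matrix(rexp(50 * 6), nrow = 50,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
  for (k in c(0.01, 1, 250))
    expect_identical(mse_filter(prof2 * k), mse_filter(prof2))
})

test_that("TF selection is a plain identifier intersection", {
  ann <- list(g1 = c("GO:0003700", "PF00001"),
              g2 = "PF09999",
              g3 = c("GO:0005515", "PF00096"),
              g4 = "PTHR11945",
              g5 = "GO:0008150")
  tf_ids <- c("GO:0003700", "PF00096", "PTHR11945", "PF00010")
  expect_setequal(select_tfs(ann, tf_ids), c("g1", "g3", "g4"))
  expect_identical(select_tfs(ann, character()), character())
  df <- data.frame(gene = c("a", "b"),
                   identifiers = c("GO:0003700;PF00001", "PF09999"))
  expect_identical(select_tfs(df, "GO:0003700"), "a")
})
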