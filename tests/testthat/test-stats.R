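test_that("all-positive signed-rank Z follows the closed form for n in 5..40", {
  for (n in 5:40) {
    t <- wilcoxon_signed_rank(seq_len(n))      # all positive, no ties
    expected <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    expect_equal(t$z, expected, tolerance = 1e-12)
    expect_equal(t$statistic, n * (n + 1) / 2)
  }
})

test_that("signed-rank test drops zeros, handles ties, matches wilcox.test p", {
  set.seed(31)
  for (i in 1:8) {
    v <- round(rnorm(25, 0.3), 2)
    v <- v[v != 0]
    t <- wilcoxon_signed_rank(v)
    ref <- suppressWarnings(
      stats::wilcox.test(v, mu = 0, exact = FALSE, correct = FALSE))
    expect_equal(t$p_raw, ref$p.value, tolerance = 1e-10)
  }
  # symmetric sample: Z = 0
  expect_equal(wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3))$z, 0)
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "undefined")
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1:6))$statistic,
               wilcoxon_signed_rank(1:6)$statistic)
})

test_that("Mann-Whitney U equals the exhaustive pair-count oracle", {
  set.seed(17)
  for (i in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(1:10, na, replace = TRUE)   # ties likely
    b <- sample(1:10, nb, replace = TRUE)
    t <- mann_whitney(a, b)
    ua <- u_pair_count(a, b)
    expect_equal(t$statistic, min(ua, na * nb - ua), tolerance = 1e-12)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(t$p_raw, ref$p.value, tolerance = 1e-10)
  }
  # complete separation and identical groups
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  tid <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tid$statistic, 9 / 2)
  expect_equal(tid$z, 0)
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("one-sided Mann-Whitney orients p-values correctly", {
  a <- c(5, 6, 7, 8); b <- c(1, 2, 3, 4)
  expect_lt(mann_whitney(a, b, alternative = "greater")$p_raw, 0.05)
  expect_gt(mann_whitney(a, b, alternative = "less")$p_raw, 0.95)
})

test_that("Spearman rho uses mid-ranks and the t approximation", {
  t <- spearman_correlation(1:5, c(1, 3, 2, 5, 4))
  expect_equal(t$statistic, 0.8, tolerance = 1e-12)   # 1 - 6*4/(5*24)
  expect_equal(spearman_correlation(1:8, exp(1:8))$statistic, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$statistic, -1)
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  t2 <- spearman_correlation(x, y)
  expect_equal(t2$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(t2$p_raw, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_correlation(rep(1, 6), 1:6), "constant")
  expect_error(spearman_correlation(1:3, 1:3), "at least 5")
})

test_that("BY adjustment matches the brute-force step-up and dominates BH", {
  # worked example: m = 4 equally spaced p-values, c(4) = 25/12
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  adj <- fdr_by(p4)$p_fdr
  expect_equal(adj, by_step_up(p4), tolerance = 1e-12)
  expect_equal(adj, rep(4 * (25 / 12) * 0.01, 4), tolerance = 1e-12)
  # m = 1: adjusted equals raw; all-ones stay one
  expect_equal(fdr_by(0.031)$p_fdr, 0.031)
  expect_equal(fdr_by(rep(1, 5))$p_fdr, rep(1, 5))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    by <- fdr_by(p)$p_fdr
    expect_equal(by, by_step_up(p), tolerance = 1e-12)
    bh <- stats::p.adjust(p, "BH")
    expect_true(all(by >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    # monotone in raw p
    expect_true(all(diff(by[order(p)]) >= -1e-12))
  }
  expect_error(fdr_by(c(0.5, 1.2)), "0, 1")
})

test_that("families are corrected separately", {
  p <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  res <- fdr_by(p, fam)
  expect_equal(res$p_fdr[1:2], res$p_fdr[3:4])
  expect_equal(res$p_fdr[1:2], by_step_up(c(0.01, 0.04)), tolerance = 1e-12)
})
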