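test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  set.seed(21)
  for (k in 1:5) {
    a <- round(rnorm(6, 10, 2), 3)
    b <- a + round(rnorm(6, 0.8, 1.2), 3)
    if (any(b == a) || any(duplicated(abs(b - a)))) next
    rep <- wilcoxon_signed_rank(a, b)
    expect_equal(rep$p_value, wilcoxon_enum_p(a, b), tolerance = 1e-12)
    expect_gte(rep$p_value, 0)
    expect_lte(rep$p_value, 1)
  }
  # a uniform positive shift gives the extreme statistic: p = 2 / 2^n
  a <- c(1, 2, 3, 4, 5, 6, 7)
  rep <- wilcoxon_signed_rank(a, a + seq(0.1, 0.7, by = 0.1))
  expect_equal(rep$p_value, 2 / 2^7, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  expect_error(wilcoxon_signed_rank(1:3, 2:4 + 0.5), "at least 5")
})

test_that("Mann-Whitney matches exhaustive group-assignment enumeration", {
  rep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(rep$statistic, 0, ignore_attr = TRUE)
  expect_equal(rep$p_value, mann_whitney_enum_p(c(1, 2), c(3, 4)),
               tolerance = 1e-12)
  set.seed(8)
  for (k in 1:5) {
    a <- round(rnorm(4, 0, 3), 3)
    b <- round(rnorm(5, 1, 3), 3)
    if (any(duplicated(c(a, b)))) next
    expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_enum_p(a, b),
                 tolerance = 1e-12)
  }
  # symmetry and identical groups
  a <- c(0.3, 1.7, 2.9)
  b <- c(0.9, 2.1, 3.3)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "data error")
})

test_that("Spearman rho, exact small-n p and Fisher-z CI behave correctly", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_ci(x, x * 2 + 1)$effect, 1)
  expect_equal(spearman_ci(x, -x)$effect, -1)
  # n = 4 fixture matches the 24-permutation enumeration
  set.seed(13)
  for (k in 1:5) {
    x4 <- round(rnorm(4), 3)
    y4 <- round(rnorm(4), 3)
    if (any(duplicated(x4)) || any(duplicated(y4))) next
    expect_equal(spearman_ci(x4, y4)$p_value, spearman_enum_p(x4, y4),
                 tolerance = 1e-12)
  }
  # CI brackets the point estimate and shrinks with n
  set.seed(2)
  x20 <- rnorm(20)
  y20 <- x20 + rnorm(20)
  rep <- spearman_ci(x20, y20)
  expect_lte(rep$ci_low, rep$effect)
  expect_gte(rep$ci_high, rep$effect)
  expect_error(spearman_ci(rep(1, 5), 1:5), "degenerate")
  expect_error(spearman_ci(1:3, 1:3), "n >= 4")
})

test_that("KS statistic equals the direct empirical-CDF computation", {
  x <- c(1.1, 2.3, 2.9, 4.2, 7.0)
  rep <- ks_normality(x)
  xs <- sort(x)
  f <- pnorm(xs, mean(x), sd(x))
  n <- length(x)
  d_hand <- max(pmax(seq_len(n) / n - f, f - (seq_len(n) - 1) / n))
  expect_equal(rep$statistic, d_hand, tolerance = 1e-12)
  expect_gte(rep$statistic, 0)
  expect_lte(rep$statistic, 1)
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "n >= 3")
})
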