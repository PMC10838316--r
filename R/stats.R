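new_stats_report <- function(test, statistic, p_value, effect = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_, n,
                             method = NA_character_) {
  tibble::tibble(
    test = test, statistic = statistic, p_value = p_value, effect = effect,
    ci_low = ci_low, ci_high = ci_high, n = as.integer(n), method = method
  )
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `paired_b - paired_a`. Zero differences are
#' dropped; for small samples without ties the exact null distribution is
#' used, otherwise the tie-corrected normal approximation (both via
#' [stats::wilcox.test()]).
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @return one-row tibble: `test`, `statistic` (V), `p_value`, `n`
#'   (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop("paired samples must have equal length")
  }
  d <- paired_b - paired_a
  nz <- d[d != 0]
  if (!length(nz)) stop("degenerate data: all paired differences are zero")
  if (length(nz) < 5L) stop("need at least 5 non-zero paired differences")
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(paired_b, paired_a, paired = TRUE, exact = exact,
                       correct = !exact)
  )
  new_stats_report(
    test = "wilcoxon_signed_rank",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n = length(nz),
    method = if (exact) "exact" else "normal_approx_tie_corrected"
  )
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum test; exact null distribution for small untied
#' groups, tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @return one-row tibble with the U statistic for `group_a`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("data error: both groups must be non-empty")
  }
  no_ties <- !any(duplicated(c(group_a, group_b)))
  exact <- min(length(group_a), length(group_b)) <= 8L && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact)
  )
  new_stats_report(
    test = "mann_whitney_u",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n = length(group_a) + length(group_b),
    method = if (exact) "exact" else "normal_approx_tie_corrected"
  )
}

#' Spearman correlation with 95% confidence interval
#'
#' Spearman's rho on average ranks. For small untied samples (n <= 9)
#' the two-sided p-value comes from the exact permutation null
#' distribution; otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. The 95% CI uses the Fisher z
#' transform with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return one-row tibble: `effect` = rho, `ci_low`, `ci_high`,
#'   `statistic` = t, `p_value`.
#' @export
spearman_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate data: constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  exact <- n <= 9L && !any(duplicated(x)) && !any(duplicated(y))
  tstat <- if (abs(rho) >= 1) sign(rho) * Inf else {
    rho * sqrt((n - 2) / (1 - rho^2))
  }
  if (exact) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)
    )
    p <- ct$p.value
  } else {
    p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  z <- atanh(pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  new_stats_report(
    test = "spearman", statistic = tstat, p_value = p, effect = rho,
    ci_low = ci[1L], ci_high = ci[2L], n = n,
    method = if (exact) "exact_permutation_fisher_z_ci" else "t_approx_fisher_z_ci"
  )
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the sample against a normal distribution
#' with the sample's own mean and standard deviation. Because the
#' parameters are estimated from the data, the reported p-value is
#' anti-conservative (Lilliefors caveat); the test is used as a
#' descriptive screen for choosing nonparametric summaries.
#'
#' @param sample numeric vector, n >= 3.
#' @return one-row tibble: `statistic` = D, `p_value` (approximate).
#' @export
ks_normality <- function(sample) {
  n <- length(sample)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(sample) == 0) stop("degenerate data: constant sample")
  kt <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean = mean(sample),
                   sd = stats::sd(sample))
  )
  new_stats_report(
    test = "ks_normality", statistic = unname(kt$statistic),
    p_value = kt$p.value, n = n,
    method = "ks_vs_fitted_normal_lilliefors_caveat"
  )
}
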