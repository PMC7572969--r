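# Brute-force / closed-form oracles are written inline and kept independent
# of the implementation paths they check.

test_that("test-retest variability reproduces hand arithmetic and symmetry", {
  expect_equal(trt_variability(1.3, 1.3), 0.0)
  expect_equal(trt_variability(1.1, 0.9), 20.0, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3); c <- runif(1, 0.1, 10)
    expect_equal(trt_variability(a, b), trt_variability(b, a))
    # invariant under common scaling
    expect_equal(trt_variability(c * a, c * b), trt_variability(a, b),
                 tolerance = 1e-12)
  }
  expect_error(trt_variability(1, -1), class = "pq_domain_error")
})

test_that("MAD outlier masks match a brute-force two-pass oracle", {
  expect_equal(mad_outliers(c(1, 2, 3, 4, 100)), c(F, F, F, F, T))
  expect_equal(mad_outliers(rep(2.5, 6)), rep(FALSE, 6))
  # degenerate MAD = 0: only values off the median flagged
  expect_equal(mad_outliers(c(1, 1, 1, 5)), c(F, F, F, T))
  oracle <- function(x, k = 3) {
    med <- median(x)
    m <- median(abs(x - med)) * 1.4826
    if (m == 0) x != med else abs(x - med) > k * m
  }
  set.seed(8)
  for (i in 1:50) {
    x <- c(rnorm(sample(3:30, 1)), if (runif(1) < 0.5) rnorm(2, 10))
    expect_identical(mad_outliers(x), oracle(x))
  }
})

test_that("agreement regression equals the closed-form normal equations", {
  g <- c(1, 1.5, 2, 2.5, 3)
  expect_equal(agreement_regression(g, g)[c("r", "slope", "intercept")],
               list(r = 1, slope = 1, intercept = 0), tolerance = 1e-12)
  a <- agreement_regression(g, 0.5 * g + 0.1)
  expect_equal(a$slope, 0.5, tolerance = 1e-12)
  expect_equal(a$intercept, 0.1, tolerance = 1e-12)
  expect_equal(a$r, 1, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    fit <- agreement_regression(x, y)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    expect_equal(fit$slope, b, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y) - b * mean(x), tolerance = 1e-10)
    expect_equal(fit$r, sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sxx * sum((y - mean(y))^2)), tolerance = 1e-10)
  }
  expect_error(agreement_regression(rep(1, 5), rnorm(5)),
               class = "pq_degenerate_error")
})

test_that("Bland-Altman statistics follow their algebraic definitions", {
  g <- seq(1, 3, 0.25)
  b0 <- bland_altman(g, g)
  expect_equal(b0$bias, 0); expect_equal(b0$loa_low, 0); expect_equal(b0$loa_high, 0)
  expect_equal(b0$trend_slope, 0)
  boff <- bland_altman(g, g + 0.2)
  expect_equal(boff$bias, 0.2, tolerance = 1e-12)
  expect_equal(boff$trend_slope, 0, tolerance = 1e-12)
  # method = 2 * gold: d = gold, mean = 1.5 gold -> trend slope 2/3
  b2 <- bland_altman(g, 2 * g)
  expect_equal(b2$trend_slope, 2 / 3, tolerance = 1e-12)
  # random data vs direct formulas
  set.seed(13)
  x <- rnorm(25, 2); y <- x + rnorm(25, 0.1, 0.2)
  bb <- bland_altman(x, y)
  d <- y - x
  expect_equal(bb$bias, mean(d), tolerance = 1e-12)
  expect_equal(bb$loa_high - bb$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)
  expect_true(bb$loa_low <= bb$bias && bb$bias <= bb$loa_high)
})

test_that("Hodges-Lehmann estimate equals full pairwise enumeration", {
  expect_equal(hodges_lehmann(c(1, 2), c(3, 4)), -2)
  expect_equal(hodges_lehmann(c(5, 5, 5), c(5, 5)), 0)
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(1:8, 1)); b <- rnorm(sample(1:8, 1)); shift <- rnorm(1)
    diffs <- c()
    for (x in a) for (y in b) diffs <- c(diffs, x - y)
    expect_equal(hodges_lehmann(a, b), median(diffs), tolerance = 1e-12)
    expect_equal(hodges_lehmann(a + shift, b), median(diffs) + shift,
                 tolerance = 1e-12)
  }
  expect_error(hodges_lehmann(numeric(0), 1), class = "pq_domain_error")
})

# Exhaustive null distribution of the rank-sum by enumerating all
# assignments of ranks to the first group.
mw_exact_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(m + n, m)
  Us <- apply(combos, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

test_that("Mann-Whitney U exact p matches exhaustive enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # 2/20 arrangements
  set.seed(15)
  for (i in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    a <- rnorm(m); b <- rnorm(n)
    res <- mann_whitney_u(a, b)
    expect_equal(res$p_value, mw_exact_oracle(a, b), tolerance = 1e-9)
    # U and U' sum to m*n
    resb <- mann_whitney_u(b, a)
    expect_equal(res$U + resb$U, m * n)
  }
})

test_that("Mann-Whitney normal approximation tracks the exact p", {
  # m = n = 10 (approximation branch) vs the exact tail from the enumerated
  # null distribution
  set.seed(16)
  for (i in 1:8) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    res <- mann_whitney_u(a, b)
    m <- 10; n <- 10
    p_exact <- min(1, 2 * min(pwilcox(res$U, m, n),
                              1 - pwilcox(res$U - 1, m, n)))
    expect_lt(abs(res$p_value - p_exact), 0.02)
  }
  # tie/continuity-corrected approximation vs wilcox.test
  set.seed(17)
  a <- sample(1:5, 10, replace = TRUE); b <- sample(2:6, 9, replace = TRUE)
  ours <- mann_whitney_u(a, b)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, wt$p.value, tolerance = 1e-9)
  expect_equal(ours$U, unname(wt$statistic))
})

test_that("paired t test equals the textbook closed form", {
  res <- paired_t_test(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  set.seed(18)
  for (i in 1:15) {
    n <- sample(3:25, 1)
    bl <- rnorm(n); fu <- bl + rnorm(n, 0.2, 0.5)
    res <- paired_t_test(bl, fu)
    d <- fu - bl
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res$t, t_oracle, tolerance = 1e-10)
    expect_equal(res$p_value, 2 * pt(-abs(t_oracle), n - 1), tolerance = 1e-10)
  }
  expect_error(paired_t_test(c(1, 2), c(2, 3)), class = "pq_degenerate_error")
})

test_that("Bonferroni adjustment caps at 1 and never decreases p", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.4, 5), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), 1), c(0.2, 0.9))
  set.seed(19)
  p <- runif(50)
  expect_true(all(bonferroni_adjust(p, 7) >= p))
})

test_that("annual percentage change and follow-up standardization formulas", {
  expect_equal(annual_percent_change(1.4, 1.4, 3), 0.0)
  expect_equal(annual_percent_change(1.0, 1.26, 2.6), 10.0, tolerance = 1e-12)
  expect_equal(annual_percent_change(1.0, 1.26, 5.2),
               annual_percent_change(1.0, 1.26, 2.6) / 2, tolerance = 1e-12)
  # scale equivariance: scaling BL and FU leaves the result unchanged
  expect_equal(annual_percent_change(3.0, 3.78, 2.6),
               annual_percent_change(1.0, 1.26, 2.6), tolerance = 1e-12)
  expect_error(annual_percent_change(0, 1, 2), class = "pq_domain_error")

  expect_equal(standardize_followup(1.0, 1.2, 2.6), 1.2)
  expect_equal(standardize_followup(1.0, 1.2, 1.3), 1.4, tolerance = 1e-12)
  expect_equal(standardize_followup(1.0, 1.2, 1.3, target_years = 2.6), 1.4)
  expect_error(standardize_followup(1, 1.2, 0), class = "pq_domain_error")
})

test_that("AIC model comparison matches hand-computed values and stats::AIC deltas", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1, 5.9)
  mc <- fit_linear_quadratic_aic(x, y)
  rss_lin <- sum(lm(y ~ x)$residuals^2)
  rss_quad <- sum(lm(y ~ x + I(x^2))$residuals^2)
  expect_equal(mc$aic_linear, 6 * log(rss_lin / 6) + 2 * 3, tolerance = 1e-9)
  expect_equal(mc$aic_quadratic, 6 * log(rss_quad / 6) + 2 * 4, tolerance = 1e-9)
  # delta agrees with stats::AIC (the Gaussian constant cancels)
  expect_equal(mc$delta_aic, AIC(lm(y ~ x)) - AIC(lm(y ~ x + I(x^2))),
               tolerance = 1e-9)
  expect_equal(mc$preferred, if (mc$delta_aic > 0) "quadratic" else "linear")
})

test_that("AIC selection prefers the generating model", {
  set.seed(20)
  # exact quadratic with curvature
  x <- seq(0.9, 2.6, length.out = 12)
  yq <- 5 - 8 * (x - 1.8)^2 + rnorm(12, 0, 0.05)
  expect_equal(fit_linear_quadratic_aic(x, yq)$preferred, "quadratic")
  # exactly linear data plus noise: linear wins in the large majority of
  # seeds (the AIC penalty of 2 admits a spurious quadratic term at the
  # asymptotic null rate P(chisq_1 > 2) ~ 16%, so ~84% is the theoretical
  # ceiling)
  pref <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 1 + 2 * x + rnorm(12, 0, 0.05)
    fit_linear_quadratic_aic(x, y)$preferred
  }, character(1))
  expect_gte(mean(pref == "linear"), 0.70)
})
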