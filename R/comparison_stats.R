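# Statistics for comparing reference regions and quantification methods:
# test-retest variability, MAD-based outlier exclusion, agreement with the
# plasma-input gold standard (linear regression + Bland-Altman),
# longitudinal SUV stability, annual amyloid accumulation with
# linear-vs-quadratic model selection, and Abeta+/- group discrimination.

#' Relative test-retest variability (percent)
#'
#' `|T - R| / (0.5 * |T + R|) * 100`; symmetric in test and retest and
#' invariant to common scaling.
#'
#' @param T,R test and retest estimates of the same quantity.
#' @export
trt_variability <- function(T, R) {
  pq_assert(is_number(T) && is_number(R), "T and R must be numbers")
  if (T + R == 0) pq_stop("T + R = 0: variability undefined", "pq_domain_error")
  abs(T - R) / (0.5 * abs(T + R)) * 100
}

#' MAD-based outlier mask (MAD3 criterion)
#'
#' Flags `x` iff `|x - median| > k * 1.4826 * median(|x_i - median|)`.
#' When the MAD is zero, only values strictly different from the median are
#' flagged.
#'
#' @param values numeric vector, length >= 3.
#' @param k multiplier (default 3, the MAD3 rule).
#' @return Logical exclusion mask.
#' @export
mad_outliers <- function(values, k = 3) {
  pq_assert(is.numeric(values) && length(values) >= 3L,
            "need at least 3 values")
  med <- stats::median(values)
  m <- 1.4826 * stats::median(abs(values - med))
  if (m == 0) return(values != med)
  abs(values - med) > k * m
}

#' Linear-regression agreement with the gold standard
#'
#' Pearson r and the OLS fit of the method value on the gold standard, so a
#' slope below 1 reads as underestimation relative to the gold standard.
#'
#' @param gold gold-standard values.
#' @param method paired method values.
#' @return Object of class `agreement_result` (`r`, `slope`, `intercept`,
#'   `n`).
#' @export
agreement_regression <- function(gold, method) {
  pq_assert(length(gold) == length(method) && length(gold) >= 3L,
            "need paired vectors of length >= 3")
  if (stats::sd(gold) == 0)
    pq_stop("gold standard is constant", "pq_degenerate_error")
  fit <- stats::lm.fit(cbind(1, gold), method)
  structure(list(r = stats::cor(gold, method),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n = length(gold)),
            class = "agreement_result")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = method - gold`; bias = mean(d); limits of agreement =
#' bias +/- 1.96 * SD(d); the trend regression of d on the pairwise mean
#' quantifies how bias depends on the underlying amyloid burden.
#'
#' @param gold,method paired vectors, length >= 3.
#' @return Object of class `bland_altman_result`.
#' @export
bland_altman <- function(gold, method) {
  if (length(gold) != length(method) || length(gold) < 3L)
    pq_stop("need paired vectors of length >= 3", "pq_insufficient_data_error")
  d <- method - gold
  m <- (method + gold) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  tr <- if (stats::sd(m) > 0) stats::lm.fit(cbind(1, m), d)$coefficients
        else c(mean(d), 0)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 trend_slope = unname(tr[2]), trend_intercept = unname(tr[1]),
                 n = length(d)),
            class = "bland_altman_result")
}

#' Hodges-Lehmann estimate of the median difference
#'
#' Median over all pairwise differences `a - b`; used as the nonparametric
#' effect size for group discrimination (called with the Abeta-negative
#' group first, giving negative effect sizes when the positive group is
#' higher).
#'
#' @param group_a,group_b numeric vectors.
#' @export
hodges_lehmann <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    pq_stop("empty group", "pq_domain_error")
  stats::median(as.numeric(outer(group_a, group_b, "-")))
}

#' Mann-Whitney U test
#'
#' U from rank sums with mid-ranks for ties. Two-sided p is exact (from the
#' enumerated null distribution) when `m + n <= 12` and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections
#' is used.
#'
#' @param group_a,group_b numeric vectors.
#' @return List with `U` (statistic of the first group) and `p_value`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  m <- length(group_a); n <- length(group_b)
  pq_assert(m >= 1L && n >= 1L, "both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (m + n <= 12 && !ties) {
    p_lo <- stats::pwilcox(U, m, n)
    p_hi <- 1 - stats::pwilcox(U - 1, m, n)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    N <- m + n
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      z <- (abs(U - m * n / 2) - 0.5) / sqrt(sigma2)  # continuity-corrected
      p <- 2 * stats::pnorm(-max(z, 0))
    }
  }
  list(U = U, p_value = p)
}

#' Paired t test
#'
#' `t = mean(d) / (SD(d)/sqrt(n))` with `d = followup - baseline`,
#' two-sided p on n - 1 degrees of freedom.
#'
#' @param baseline,followup paired vectors, n >= 2.
#' @return List with `t`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(baseline, followup) {
  pq_assert(length(baseline) == length(followup) && length(baseline) >= 2L,
            "need paired vectors of length >= 2")
  d <- followup - baseline
  if (stats::sd(d) == 0)
    pq_stop("zero variance of paired differences", "pq_degenerate_error")
  ht <- stats::t.test(followup, baseline, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d))
}

#' Bonferroni adjustment with explicit family size
#'
#' `p_adj = min(1, m * p)`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m family size (>= 1).
#' @export
bonferroni_adjust <- function(p_values, m) {
  pq_assert(is_number(m) && m >= 1, "family size m must be >= 1")
  pq_assert(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Annual percentage change
#'
#' `((FU - BL) / years) * (100 / BL)`, in percent per year.
#'
#' @param BL baseline value (non-zero).
#' @param FU follow-up value.
#' @param years follow-up interval (> 0).
#' @export
annual_percent_change <- function(BL, FU, years) {
  if (!is_number(BL) || BL == 0) pq_stop("BL must be non-zero", "pq_domain_error")
  if (!is_number(years) || years <= 0)
    pq_stop("years must be > 0", "pq_domain_error")
  ((FU - BL) / years) * (100 / BL)
}

#' Standardize a follow-up value to a common follow-up time
#'
#' Linear-in-time rescaling of the observed change:
#' `BL + (FU - BL) * target_years / years`. The default target (2.6 years)
#' is the cohort-average follow-up time.
#'
#' @param BL,FU baseline and follow-up values.
#' @param years actual follow-up interval (> 0).
#' @param target_years target interval (default 2.6).
#' @export
standardize_followup <- function(BL, FU, years, target_years = 2.6) {
  if (!is_number(years) || years <= 0)
    pq_stop("years must be > 0", "pq_domain_error")
  BL + (FU - BL) * (target_years / years)
}

#' Linear vs quadratic model comparison by AIC
#'
#' OLS fits of `y = a + b*x` and `y = a + b*x + c*x^2`;
#' `AIC = n*log(RSS/n) + 2*k` with k = number of coefficients + 1 (error
#' variance). The quadratic model is preferred iff
#' `delta_aic = aic_linear - aic_quadratic > 0`.
#'
#' @param x predictor (e.g. baseline amyloid burden), not constant.
#' @param y response (e.g. annual percentage change).
#' @return Object of class `model_comparison_result`.
#' @export
fit_linear_quadratic_aic <- function(x, y) {
  pq_assert(length(x) == length(y) && length(x) >= 4L,
            "need paired vectors of length >= 4")
  if (stats::sd(x) == 0) pq_stop("constant predictor", "pq_numeric_error")
  n <- length(x)
  fit_one <- function(X, k_coef) {
    f <- stats::lm.fit(X, y)
    if (any(is.na(f$coefficients)))
      pq_stop("degenerate design matrix", "pq_numeric_error")
    rss <- sum(f$residuals^2)
    list(coef = f$coefficients, rss = rss,
         aic = n * log(rss / n) + 2 * (k_coef + 1))
  }
  lin <- fit_one(cbind(`(Intercept)` = 1, x = x), 2L)
  quad <- fit_one(cbind(`(Intercept)` = 1, x = x, x2 = x^2), 3L)
  delta <- lin$aic - quad$aic
  structure(list(aic_linear = lin$aic, aic_quadratic = quad$aic,
                 delta_aic = delta,
                 preferred = if (delta > 0) "quadratic" else "linear",
                 coef_linear = lin$coef, coef_quadratic = quad$coef,
                 n = n),
            class = "model_comparison_result")
}
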