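# Internal helpers: classed conditions and piecewise-linear integration.

pq_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pq_error", "error", "condition")))
}

pq_assert <- function(ok, msg, class = "pq_validation_error") {
  if (!isTRUE(ok)) pq_stop(msg, class)
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Exact integral of the piecewise-linear curve through (knots, vals) over
# [t0, t1]; knots strictly increasing, t0 <= t1 inside [min, max] of knots.
plin_integral <- function(knots, vals, t0, t1) {
  v0 <- stats::approx(knots, vals, xout = t0)$y
  v1 <- stats::approx(knots, vals, xout = t1)$y
  inner <- knots > t0 & knots < t1
  tt <- c(t0, knots[inner], t1)
  vv <- c(v0, vals[inner], v1)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}

# Cumulative trapezoid along a sampled curve (same length as x).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}
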