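# Plasma-input and reference-tissue kinetic models for reversible tracers.
#
# Forward models are evaluated analytically: the impulse response of the
# reversible two-tissue system (and of SRTM) is a sum of exponentials, and
# the convolution of a piecewise-linear input with exp(-a*t) is computed
# exactly on a uniform fine grid via a linear recurrence (stats::filter),
# so simulation error is only input-interpolation error. Frame values are
# exact trapezoid averages of the fine-grid curve over each frame window.

FINE_DT <- 0.05  # minutes; fine-grid spacing for convolution

# Exact convolution of the piecewise-linear curve f (on a uniform grid with
# spacing dt, f[1] at t=0) with exp(-a*t).
conv_exp <- function(f, dt, a) {
  n <- length(f)
  if (a < 0) pq_stop("negative rate in convolution", "pq_numeric_error")
  adt <- a * dt
  E <- exp(-adt)
  if (adt < 1e-3) {
    I0 <- dt * (1 - adt / 2 + adt^2 / 6)
    I1 <- dt^2 * (1 / 2 - adt / 3 + adt^2 / 8)
  } else {
    I0 <- (1 - E) / a
    I1 <- (1 - E * (1 + adt)) / a^2
  }
  # increment over one step: f_i*I0 + (f_{i-1} - f_i)*I1/dt
  x <- c(0, f[-1] * (I0 - I1 / dt) + f[-n] * (I1 / dt))
  as.numeric(stats::filter(x, E, method = "recursive"))
}

# Average of the fine-grid curve over each frame window (exact trapezoid).
frame_average <- function(grid, values, schedule) {
  cc <- cumtrapz(grid, values)
  Fa <- stats::approx(grid, cc, xout = schedule$start_times)$y
  Fb <- stats::approx(grid, cc, xout = schedule$start_times + schedule$durations)$y
  (Fb - Fa) / schedule$durations
}

uniform_input_grid <- function(input, t_end, dt = FINE_DT) {
  if (max(input$times) < t_end - 1e-9)
    pq_stop("input function does not cover the scan", "pq_range_error")
  grid <- seq(0, t_end, by = dt)
  list(grid = grid,
       plasma = stats::approx(input$times, input$plasma_parent, xout = grid)$y,
       blood = stats::approx(input$times, input$whole_blood, xout = grid)$y)
}

#' Micro-parameters of the reversible two-tissue model (2T4k_Vb)
#'
#' @param K1 plasma-to-tissue delivery (mL cm^-3 min^-1).
#' @param k2,k3,k4 tissue rate constants (min^-1); `k3 = 0` means no
#'   specific binding.
#' @param Vb fractional blood volume, in `[0, 1)`.
#' @return Object of class `kinetic_params_2t4k` with the derived volume of
#'   distribution `VT = (K1/k2) * (1 + k3/k4)`.
#' @export
kinetic_params_2t4k <- function(K1, k2, k3 = 0, k4 = 0.05, Vb = 0) {
  pq_assert(K1 > 0 && k2 > 0 && k4 > 0, "K1, k2, k4 must be positive")
  pq_assert(k3 >= 0, "k3 must be >= 0")
  pq_assert(Vb >= 0 && Vb < 1, "Vb must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb,
                 VT = vt_from_micro(K1, k2, k3, k4)),
            class = "kinetic_params_2t4k")
}

#' Volume of distribution from micro-parameters
#'
#' `VT = (K1/k2) * (1 + k3/k4)`; reduces to `K1/k2` when `k3 = 0`.
#'
#' @param K1,k2,k3,k4 rate constants, `K1, k2 > 0`, `k3 >= 0`.
#' @export
vt_from_micro <- function(K1, k2, k3, k4) {
  pq_assert(K1 > 0 && k2 > 0, "K1 and k2 must be positive")
  pq_assert(k3 >= 0, "k3 must be >= 0")
  if (k3 > 0 && k4 <= 0)
    pq_stop("k4 = 0 with k3 > 0: irreversible model has no finite VT",
            "pq_domain_error")
  if (k3 == 0) K1 / k2 else (K1 / k2) * (1 + k3 / k4)
}

#' Distribution volume ratio
#'
#' `DVR = VT(target) / VT(reference)`. With the validated cerebellar grey
#' matter as reference this is the plasma-input gold standard (DVR_PI_GMCB).
#'
#' @param vt_target,vt_reference volumes of distribution.
#' @export
dvr_from_vt <- function(vt_target, vt_reference) {
  pq_assert(is_number(vt_target), "vt_target must be a number")
  if (!is_number(vt_reference) || vt_reference <= 0)
    pq_stop("vt_reference must be > 0", "pq_domain_error")
  vt_target / vt_reference
}

# Exponents and coefficients of the 2T4k impulse response
# h(t) = B1*exp(-a1*t) + B2*exp(-a2*t).
twotc_irf <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 0) pq_stop("negative discriminant in 2T4k impulse response",
                        "pq_numeric_error")
  r <- sqrt(disc)
  a1 <- (s - r) / 2
  a2 <- (s + r) / 2
  if (a2 - a1 < 1e-9) {  # coincident exponents: nudge (measure-zero case)
    a2 <- a1 + 1e-9
  }
  B1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  B2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  list(a1 = a1, a2 = a2, B1 = B1, B2 = B2)
}

twotc_fine_curve <- function(K1, k2, k3, k4, Vb, plasma, blood, dt) {
  h <- twotc_irf(K1, k2, k3, k4)
  ct <- h$B1 * conv_exp(plasma, dt, h$a1) + h$B2 * conv_exp(plasma, dt, h$a2)
  (1 - Vb) * ct + Vb * blood
}

#' Simulate a 2T4k_Vb time-activity curve
#'
#' Tissue response = analytic bi-exponential impulse response convolved with
#' the metabolite-corrected plasma curve; the measured value is
#' `(1 - Vb) * C_tissue + Vb * C_wholeblood`, averaged over each frame.
#'
#' @param params a [kinetic_params_2t4k()].
#' @param input an [input_function()] covering the scan.
#' @param schedule a [frame_schedule()].
#' @param region_label,volume_ml passed to the returned [tac()].
#' @return A [tac()] of frame values.
#' @export
simulate_2t4k <- function(params, input, schedule,
                          region_label = "sim", volume_ml = NULL) {
  stopifnot(inherits(params, "kinetic_params_2t4k"),
            inherits(input, "input_function"),
            inherits(schedule, "frame_schedule"))
  u <- uniform_input_grid(input, scan_end(schedule))
  fine <- twotc_fine_curve(params$K1, params$k2, params$k3, params$k4,
                           params$Vb, u$plasma, u$blood, FINE_DT)
  tac(schedule, frame_average(u$grid, fine, schedule),
      region_label = region_label, volume_ml = volume_ml)
}

#' Fit diagnostics
#' @param rss residual sum of squares.
#' @param converged logical.
#' @param n_iterations iteration count of the winning start.
#' @param at_bound named logical vector, parameter at a box bound.
#' @export
fit_diagnostics <- function(rss, converged, n_iterations, at_bound) {
  pq_assert(rss >= 0, "RSS must be non-negative")
  structure(list(residual_sum_squares = rss, converged = converged,
                 n_iterations = n_iterations, parameter_at_bound = at_bound),
            class = "fit_diagnostics")
}

default_2t4k_bounds <- function() {
  list(lower = c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, k4 = 1e-4, Vb = 0),
       upper = c(K1 = 2, k2 = 1, k3 = 1, k4 = 1, Vb = 0.15))
}

default_srtm_bounds <- function() {
  list(lower = c(R1 = 0.1, k2 = 0.006, BPnd = -0.5),
       upper = c(R1 = 3, k2 = 0.6, BPnd = 10))
}

resolve_weights <- function(weights, schedule) {
  if (is.null(weights) || identical(weights, "duration"))
    return(schedule$durations)
  if (identical(weights, "uniform")) return(rep(1, length(schedule)))
  pq_assert(is.numeric(weights) && length(weights) == length(schedule) &&
              all(weights >= 0), "weights must match frame count and be >= 0")
  weights
}

# Deterministic multi-start points: the start-box midpoint (geometric for
# strictly positive parameters) plus log/linear-uniform draws. The start box
# may be narrower than the admissible bounds: rate constants admissible over
# (1e-4, 1] span physiologic values only over a small sub-interval, and
# starts drawn log-uniformly over the whole box land far from any plausible
# optimum.
multi_starts <- function(lower, upper, n_starts, seed) {
  pos <- lower > 0
  lo <- pmax(lower, 1e-12)
  mid <- (lower + upper) / 2
  mid[pos] <- sqrt(lo[pos] * upper[pos])
  starts <- list(mid)
  if (n_starts > 1L) {
    rs <- local({
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
      set.seed(seed %% .Machine$integer.max)
      lapply(seq_len(n_starts - 1L), function(i) {
        u <- stats::runif(length(lower))
        s <- lower + u * (upper - lower)
        s[pos] <- exp(log(lo[pos]) + u[pos] * (log(upper[pos]) - log(lo[pos])))
        s
      })
    })
    starts <- c(starts, rs)
  }
  starts
}

run_multistart_fit <- function(resid_fn, lower, upper, n_starts, seed,
                               start_lower = lower, start_upper = upper) {
  sl <- pmin(pmax(start_lower, lower), upper)
  su <- pmin(pmax(start_upper, lower), upper)
  starts <- multi_starts(sl, su, n_starts, seed)
  best <- NULL
  one_fit <- function(p0) tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  for (p0 in starts) {
    fit <- one_fit(p0)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info,
                   niter = fit$niter)
  }
  if (is.null(best))
    pq_stop("model fit failed to converge from every start", "pq_fit_error")
  polish <- one_fit(best$par)  # restart once from the winner
  if (!is.null(polish) && sum(polish$fvec^2) < best$rss)
    best <- list(par = polish$par, rss = sum(polish$fvec^2),
                 info = polish$info, niter = best$niter + polish$niter)
  best
}

# Physiologic start boxes for PiB-like tracers (starts only; the admissible
# bounds are unchanged).
start_box_2t4k <- function() {
  list(lower = c(K1 = 0.05, k2 = 0.02, k3 = 0.002, k4 = 0.01, Vb = 0.01),
       upper = c(K1 = 0.6, k2 = 0.4, k3 = 0.2, k4 = 0.2, Vb = 0.08))
}

#' Fit the plasma-input 2T4k_Vb model to a TAC
#'
#' Bounded weighted least squares against [simulate_2t4k()], best of
#' `n_starts` deterministic multi-starts.
#'
#' @param x target [tac()].
#' @param input an [input_function()].
#' @param weights `"duration"` (default, w_i = frame duration), `"uniform"`,
#'   or a numeric vector per frame.
#' @param bounds list with named `lower`/`upper` vectors over
#'   `K1, k2, k3, k4, Vb`.
#' @param n_starts number of optimizer starts.
#' @param seed seed for the random starts (deterministic fits).
#' @return List with `params` ([kinetic_params_2t4k()], VT populated) and
#'   `diagnostics` ([fit_diagnostics()]).
#' @export
fit_2t4k_vb <- function(x, input, weights = "duration",
                        bounds = default_2t4k_bounds(),
                        n_starts = 5, seed = 1) {
  stopifnot(inherits(x, "tac"), inherits(input, "input_function"))
  sched <- x$schedule
  w <- resolve_weights(weights, sched)
  sw <- sqrt(w)
  u <- uniform_input_grid(input, scan_end(sched))
  obs <- x$values
  resid_fn <- function(p) {
    sim <- frame_average(u$grid,
                         twotc_fine_curve(p[1], p[2], p[3], p[4], p[5],
                                          u$plasma, u$blood, FINE_DT),
                         sched)
    sw * (sim - obs)
  }
  lower <- bounds$lower[c("K1", "k2", "k3", "k4", "Vb")]
  upper <- bounds$upper[c("K1", "k2", "k3", "k4", "Vb")]
  sb <- start_box_2t4k()
  best <- run_multistart_fit(resid_fn, lower, upper, n_starts, seed,
                             start_lower = sb$lower, start_upper = sb$upper)
  p <- best$par
  names(p) <- c("K1", "k2", "k3", "k4", "Vb")
  span <- pmax(upper - lower, 1e-12)
  at_bound <- (p - lower) / span < 1e-4 | (upper - p) / span < 1e-4
  params <- kinetic_params_2t4k(p[["K1"]], p[["k2"]], p[["k3"]], p[["k4"]],
                                p[["Vb"]])
  list(params = params,
       diagnostics = fit_diagnostics(best$rss, best$info %in% 1:3,
                                     best$niter, at_bound))
}

#' Reference Logan graphical analysis
#'
#' Ordinary least-squares slope of
#' `y(T) = int_0^T C_target / C_target(T)` on
#' `x(T) = int_0^T C_ref / C_target(T)` over frames with mid-time strictly
#' greater than the linearization time `t_star`; the slope is reported as
#' DVR (the k2' term is omitted).
#'
#' @param target,reference [tac()]s on a shared schedule.
#' @param t_star linearization time in minutes (default 50).
#' @return Object of class `rlogan_result` with `DVR`, `intercept`,
#'   `t_star`, `n_points`, `r_squared`.
#' @export
rlogan_dvr <- function(target, reference, t_star = 50) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  mids <- frame_midtimes(target$schedule)
  sel <- which(mids > t_star)
  if (length(sel) < 3L)
    pq_stop("fewer than 3 frames beyond t_star", "pq_insufficient_data_error")
  if (any(target$values[sel] <= 0))
    pq_stop("non-positive target activity in the Logan window", "pq_domain_error")
  if (any(reference$values[sel] <= 0))
    pq_stop("non-positive reference activity in the Logan window", "pq_domain_error")
  int_at_mids <- function(x) {
    k <- tac_knots(x)
    cumtrapz(k$t, k$v)[seq_along(mids) + 1L]
  }
  it <- int_at_mids(target)
  ir <- int_at_mids(reference)
  ct <- target$values
  xx <- (ir / ct)[sel]
  yy <- (it / ct)[sel]
  fit <- stats::lm.fit(cbind(1, xx), yy)
  slope <- fit$coefficients[2]
  icpt <- fit$coefficients[1]
  r2 <- 1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
  structure(list(DVR = unname(slope), intercept = unname(icpt),
                 t_star = t_star, n_points = length(sel), r_squared = r2),
            class = "rlogan_result")
}

#' SRTM parameters
#'
#' @param R1 relative delivery (target K1 / reference K1').
#' @param k2 target efflux rate (min^-1).
#' @param BPnd non-displaceable binding potential (> -1).
#' @return Object of class `srtm_params` with `DVR = BPnd + 1`.
#' @export
srtm_params <- function(R1, k2, BPnd) {
  pq_assert(R1 > 0 && k2 > 0, "R1 and k2 must be positive")
  if (BPnd <= -1) pq_stop("BPnd must be > -1", "pq_domain_error")
  structure(list(R1 = R1, k2 = k2, BPnd = BPnd, DVR = BPnd + 1),
            class = "srtm_params")
}

#' Simulate an SRTM time-activity curve
#'
#' `C_t(t) = R1*C_ref(t) + (k2 - R1*k2a) * (C_ref (x) exp(-k2a*t))` with
#' `k2a = k2 / (1 + BPnd)`, evaluated by fine-grid convolution then sampling
#' at the frame mid-times (so the BPnd = 0, R1 = 1 identity is exact).
#'
#' @param params an [srtm_params()].
#' @param reference the reference-region [tac()].
#' @param region_label,volume_ml passed to the returned [tac()].
#' @return A [tac()] on the reference schedule.
#' @export
simulate_srtm <- function(params, reference, region_label = "sim",
                          volume_ml = NULL) {
  stopifnot(inherits(params, "srtm_params"), inherits(reference, "tac"))
  sched <- reference$schedule
  k <- tac_knots(reference)
  grid <- seq(0, scan_end(sched), by = FINE_DT)
  ref_fine <- stats::approx(k$t, k$v, xout = grid)$y
  k2a <- params$k2 / (1 + params$BPnd)
  cv <- conv_exp(ref_fine, FINE_DT, k2a)
  vals <- params$R1 * reference$values +
    (params$k2 - params$R1 * k2a) *
      stats::approx(grid, cv, xout = frame_midtimes(sched))$y
  tac(sched, vals, region_label = region_label, volume_ml = volume_ml)
}

#' Fit the simplified reference tissue model
#'
#' Bounded weighted least squares against [simulate_srtm()]; per
#' reference-region fit boundaries may be supplied via `bounds`.
#'
#' @param target,reference [tac()]s on a shared schedule.
#' @param weights as in [fit_2t4k_vb()].
#' @param bounds list with named `lower`/`upper` vectors over
#'   `R1, k2, BPnd`.
#' @param n_starts,seed multi-start control.
#' @return List with `params` ([srtm_params()], `DVR = BPnd + 1`) and
#'   `diagnostics`.
#' @export
fit_srtm <- function(target, reference, weights = "duration",
                     bounds = default_srtm_bounds(), n_starts = 5, seed = 1) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  sched <- target$schedule
  w <- resolve_weights(weights, sched)
  sw <- sqrt(w)
  k <- tac_knots(reference)
  grid <- seq(0, scan_end(sched), by = FINE_DT)
  ref_fine <- stats::approx(k$t, k$v, xout = grid)$y
  obs <- target$values
  mids <- frame_midtimes(sched)
  ref_mid <- reference$values
  resid_fn <- function(p) {
    k2a <- p[2] / (1 + p[3])
    cv <- stats::approx(grid, conv_exp(ref_fine, FINE_DT, k2a), xout = mids)$y
    sw * (p[1] * ref_mid + (p[2] - p[1] * k2a) * cv - obs)
  }
  lower <- bounds$lower[c("R1", "k2", "BPnd")]
  upper <- bounds$upper[c("R1", "k2", "BPnd")]
  best <- run_multistart_fit(resid_fn, lower, upper, n_starts, seed)
  p <- best$par
  names(p) <- c("R1", "k2", "BPnd")
  span <- pmax(upper - lower, 1e-12)
  at_bound <- (p - lower) / span < 1e-4 | (upper - p) / span < 1e-4
  params <- srtm_params(p[["R1"]], p[["k2"]], p[["BPnd"]])
  list(params = params,
       diagnostics = fit_diagnostics(best$rss, best$info %in% 1:3,
                                     best$niter, at_bound))
}
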