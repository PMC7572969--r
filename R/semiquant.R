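# Standardized uptake values (SUV) and ratios (SUVr) over acquisition
# windows. Window means are time-integrals over the window divided by the
# window length, so unequal frame durations and partial frame overlap are
# handled exactly.

#' Create an SUV acquisition window
#'
#' @param t0,t1 window limits in minutes, `0 <= t0 < t1`.
#' @param label window label; defaults to `"t0-t1"`.
#' @return Object of class `suv_window`.
#' @export
suv_window_def <- function(t0, t1, label = sprintf("%g-%g", t0, t1)) {
  pq_assert(is_number(t0) && is_number(t1) && t0 >= 0 && t0 < t1,
            "need 0 <= t0 < t1")
  structure(list(t0 = t0, t1 = t1, label = label), class = "suv_window")
}

#' The two standard PiB acquisition windows (40-60 and 60-90 min p.i.)
#' @export
default_suv_windows <- function() {
  list(`40-60` = suv_window_def(40, 60, "40-60"),
       `60-90` = suv_window_def(60, 90, "60-90"))
}

window_mean <- function(x, window) {
  integrate_tac(x, window$t0, window$t1) / (window$t1 - window$t0)
}

#' Standardized uptake value over a window
#'
#' Mean activity concentration over the window divided by injected dose per
#' body weight; with activity in kBq/mL, dose in MBq and weight in kg the
#' result is in g/mL.
#'
#' @param x a [tac()].
#' @param dose_MBq injected dose (MBq).
#' @param weight_kg body weight (kg).
#' @param window an [suv_window_def()].
#' @export
suv_window <- function(x, dose_MBq, weight_kg, window) {
  stopifnot(inherits(x, "tac"), inherits(window, "suv_window"))
  if (is.null(dose_MBq) || is.null(weight_kg))
    pq_stop("injected dose / weight unavailable: SUV cannot be computed",
            "pq_unavailable_error")
  pq_assert(is_number(dose_MBq) && dose_MBq > 0, "dose must be > 0")
  pq_assert(is_number(weight_kg) && weight_kg > 0, "weight must be > 0")
  # dose_MBq*1000 kBq / (weight_kg*1000 g) = dose/weight in kBq/g
  window_mean(x, window) / (dose_MBq / weight_kg)
}

#' Standardized uptake value ratio over a window
#'
#' Ratio of target to reference window means; dose and weight cancel.
#'
#' @param target,reference [tac()]s on a shared schedule.
#' @param window an [suv_window_def()].
#' @export
suvr_window <- function(target, reference, window) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"),
            inherits(window, "suv_window"))
  ref_mean <- window_mean(reference, window)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    pq_stop("non-positive reference window mean", "pq_domain_error")
  window_mean(target, window) / ref_mean
}
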