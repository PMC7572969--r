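# Metabolite-corrected plasma input construction.
#
# The plasma-input model needs two curves on a fine time grid: the
# metabolite-corrected plasma activity of parent tracer (C_p) and the
# whole-blood activity (C_wb, for the fractional blood-volume term).
# Discrete whole-blood samples are interpolated, then corrected with the
# time-varying plasma-to-whole-blood ratio and plasma parent fraction.

#' Create an input function
#'
#' @param times fine time grid (minutes), strictly increasing, starting at 0.
#' @param plasma_parent metabolite-corrected plasma activity (kBq/mL).
#' @param whole_blood whole-blood activity (kBq/mL) on the same grid.
#' @return An object of class `input_function`.
#' @export
input_function <- function(times, plasma_parent, whole_blood) {
  pq_assert(length(times) >= 2L && all(diff(times) > 0),
            "times must be strictly increasing")
  pq_assert(abs(times[1]) < 1e-9, "time grid must start at 0")
  pq_assert(length(plasma_parent) == length(times) &&
              length(whole_blood) == length(times),
            "curve lengths must match the grid")
  pq_assert(all(is.finite(plasma_parent)) && all(is.finite(whole_blood)),
            "input curves must be finite")
  pq_assert(all(plasma_parent >= -1e-12) && all(whole_blood >= -1e-12),
            "input curves must be non-negative")
  structure(list(times = as.numeric(times),
                 plasma_parent = pmax(as.numeric(plasma_parent), 0),
                 whole_blood = pmax(as.numeric(whole_blood), 0)),
            class = "input_function")
}

#' Create a correction model
#'
#' Holds the time-varying plasma-to-whole-blood activity ratio and the
#' plasma parent fraction. Each may be given as a function of time or as a
#' two-column table `(time_min, value)` which is interpolated linearly
#' (constant beyond the last sample).
#'
#' @param plasma_to_wholeblood ratio model (dimensionless, > 0).
#' @param parent_fraction parent-fraction model (in `[0, 1]`,
#'   `parent_fraction(0) = 1` within 0.05).
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(plasma_to_wholeblood, parent_fraction) {
  as_fun <- function(m, what) {
    if (is.function(m)) return(m)
    if (is.data.frame(m) && ncol(m) >= 2L)
      return(stats::approxfun(m[[1]], m[[2]], rule = 2))
    pq_stop(paste(what, "must be a function or a (time, value) table"),
            "pq_validation_error")
  }
  pf <- as_fun(parent_fraction, "parent_fraction")
  pq_assert(abs(pf(0) - 1) <= 0.05, "parent_fraction(0) must be 1",
            "pq_validation_error")
  structure(list(plasma_to_wholeblood = as_fun(plasma_to_wholeblood, "ratio"),
                 parent_fraction = pf),
            class = "correction_model")
}

#' Resample a sampled curve onto a new grid by linear interpolation
#'
#' The curve is pinned to 0 at t = 0 when the first sample is later than 0.
#' Requests beyond the last sample raise a range error (no tail
#' extrapolation).
#'
#' @param times,values the sampled curve.
#' @param new_grid query times.
#' @return Values on `new_grid`.
#' @export
resample_curve <- function(times, values, new_grid) {
  pq_assert(length(times) == length(values) && length(times) >= 1L,
            "times/values must be equal length")
  pq_assert(all(diff(times) > 0), "times must be strictly increasing")
  if (times[1] > 1e-12) {
    times <- c(0, times)
    values <- c(0, values)
  }
  if (max(new_grid) > times[length(times)] + 1e-9 || min(new_grid) < times[1] - 1e-9)
    pq_stop("new_grid extends beyond the sampled range", "pq_range_error")
  stats::approx(times, values, xout = new_grid)$y
}

#' Derive the metabolite-corrected plasma input function
#'
#' `plasma_parent(t) = whole_blood(t) * plasma_to_wholeblood(t) *
#' parent_fraction(t)`, with the whole-blood samples linearly interpolated
#' and pinned to 0 at t = 0.
#'
#' @param whole_blood_samples data frame or list with `time_min` and
#'   `whole_blood_kBq_ml` (at least two samples spanning the grid).
#' @param corrections a [correction_model()].
#' @param grid fine output grid (minutes), starting at 0.
#' @return An [input_function()] holding both curves on `grid`.
#' @export
derive_plasma_input <- function(whole_blood_samples, corrections, grid) {
  stopifnot(inherits(corrections, "correction_model"))
  s <- whole_blood_samples
  pq_assert(!is.null(s$time_min) && !is.null(s$whole_blood_kBq_ml),
            "whole_blood_samples needs time_min and whole_blood_kBq_ml")
  pq_assert(length(s$time_min) >= 2L, "need at least two whole-blood samples")
  wb <- resample_curve(s$time_min, s$whole_blood_kBq_ml, grid)
  ratio <- corrections$plasma_to_wholeblood(grid)
  pf <- corrections$parent_fraction(grid)
  pq_assert(all(is.finite(ratio)) && all(ratio > 0),
            "plasma-to-whole-blood ratio must be positive")
  pq_assert(all(is.finite(pf)) && all(pf >= -1e-12) && all(pf <= 1 + 1e-12),
            "parent fraction must lie in [0, 1]")
  input_function(grid, wb * ratio * pmin(pmax(pf, 0), 1), wb)
}

#' Read a blood table
#'
#' Delimited text with columns `time_min`, `whole_blood_kBq_ml` and
#' optionally `plasma_to_wb_ratio` and `parent_fraction`. Missing correction
#' columns default to ratio 1 and parent fraction 1.
#'
#' @param path file path.
#' @return List with `samples` (data frame) and `corrections`
#'   (a [correction_model()]).
#' @export
read_blood_table <- function(path) {
  pq_assert(file.exists(path), "blood table not found", "pq_io_error")
  df <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                          stringsAsFactors = FALSE)
  pq_assert(all(c("time_min", "whole_blood_kBq_ml") %in% names(df)),
            "blood table needs time_min and whole_blood_kBq_ml columns",
            "pq_format_error")
  ratio <- if ("plasma_to_wb_ratio" %in% names(df))
    data.frame(df$time_min, df$plasma_to_wb_ratio) else function(t) rep(1, length(t))
  pf <- if ("parent_fraction" %in% names(df))
    data.frame(df$time_min, df$parent_fraction) else function(t) rep(1, length(t))
  list(samples = df[c("time_min", "whole_blood_kBq_ml")],
       corrections = correction_model(ratio, pf))
}

#' Write a blood table
#' @param samples data frame with `time_min`, `whole_blood_kBq_ml` and
#'   optionally `plasma_to_wb_ratio`, `parent_fraction`.
#' @param path output path.
#' @export
write_blood_table <- function(samples, path) {
  write_table_full(as.data.frame(samples), path)
  invisible(NULL)
}
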