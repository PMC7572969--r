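# Domain types for dynamic-PET frame schedules, regional time-activity
# curves (TACs) and scan sessions, plus delimited-text I/O.
#
# Conventions used throughout the package:
#   * time is in minutes post injection, activity in kBq/mL (decay-corrected
#     to injection time upstream);
#   * a frame value is treated as an instantaneous sample at the frame
#     mid-time; the continuous curve is piecewise linear through (0, 0) and
#     the mid-time samples, and constant from the last mid-time to scan end.

#' Reference-region labels recognised by the pipeline
#'
#' Cerebellar grey matter (GMCB), whole cerebellum (WCB), white-matter
#' brainstem/pons (WMBS), whole brainstem (WBS) and eroded subcortical white
#' matter (WMES).
#' @export
REFERENCE_REGIONS <- c("GMCB", "WCB", "WMBS", "WBS", "WMES")

#' Quantification method labels of the parameter table
#' @export
DVR_METHODS <- c("DVR_PI", "DVR_RLOGAN", "DVR_SRTM", "SUVR_40_60", "SUVR_60_90")

#' Create a frame schedule
#'
#' @param start_times frame start times (minutes), strictly increasing.
#' @param durations frame durations (minutes), all positive; frames must not
#'   overlap.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(start_times, durations) {
  pq_assert(is.numeric(start_times) && is.numeric(durations),
            "start_times and durations must be numeric")
  pq_assert(length(start_times) == length(durations) && length(start_times) >= 1L,
            "start_times and durations must have equal, positive length")
  pq_assert(all(is.finite(start_times)) && all(is.finite(durations)),
            "frame times must be finite")
  pq_assert(all(durations > 0), "frame durations must be positive")
  pq_assert(all(diff(start_times) > 0), "frame start times must be strictly increasing")
  n <- length(start_times)
  if (n > 1L) {
    ends <- start_times[-n] + durations[-n]
    pq_assert(all(ends <= start_times[-1] + 1e-9), "frames overlap")
  }
  structure(list(start_times = as.numeric(start_times),
                 durations = as.numeric(durations)),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_times)

#' Frame mid-times
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector `start + duration/2` per frame.
#' @export
frame_midtimes <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$start_times + schedule$durations / 2
}

#' Scan end time (minutes)
#' @param schedule a [frame_schedule()].
#' @export
scan_end <- function(schedule) {
  n <- length(schedule$start_times)
  schedule$start_times[n] + schedule$durations[n]
}

#' Create a regional time-activity curve
#'
#' @param schedule a [frame_schedule()].
#' @param values activity concentration (kBq/mL), one per frame.
#' @param region_label region name.
#' @param volume_ml optional region volume (mL), used for volume-weighted
#'   composite regions.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region_label = "region", volume_ml = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  pq_assert(is.numeric(values) && length(values) == length(schedule),
            "values length must equal frame count")
  pq_assert(all(is.finite(values)), "TAC values must be finite")
  if (!is.null(volume_ml))
    pq_assert(is_number(volume_ml) && volume_ml > 0, "volume_ml must be > 0")
  structure(list(schedule = schedule, values = as.numeric(values),
                 region_label = as.character(region_label),
                 volume_ml = volume_ml),
            class = "tac")
}

# Knots of the continuous (piecewise linear) curve a TAC represents:
# (0, 0), the mid-time samples, and a constant tail to scan end.
tac_knots <- function(x) {
  mids <- frame_midtimes(x$schedule)
  tend <- scan_end(x$schedule)
  kt <- c(0, mids)
  kv <- c(0, x$values)
  if (tend > mids[length(mids)] + 1e-12) {
    kt <- c(kt, tend)
    kv <- c(kv, x$values[length(x$values)])
  }
  list(t = kt, v = kv)
}

#' Integrate a TAC over a time window
#'
#' Trapezoidal integral of the mid-time-sampled curve, taken as 0 at t = 0,
#' linearly interpolated between samples and constant after the last
#' mid-time.
#'
#' @param x a [tac()].
#' @param t0,t1 window limits in minutes, `0 <= t0 < t1 <= scan end`.
#' @return Integral in kBq*min/mL.
#' @export
integrate_tac <- function(x, t0, t1) {
  stopifnot(inherits(x, "tac"))
  pq_assert(is_number(t0) && is_number(t1) && t0 < t1,
            "need t0 < t1", "pq_range_error")
  tend <- scan_end(x$schedule)
  if (t0 < -1e-9 || t1 > tend + 1e-9)
    pq_stop(sprintf("window [%g, %g] outside scan [0, %g]", t0, t1, tend),
            "pq_range_error")
  k <- tac_knots(x)
  plin_integral(k$t, k$v, max(t0, 0), min(t1, tend))
}

#' Volume-weighted composite value over target regions
#'
#' The composite global cortical measure is the volume-weighted average of
#' the regional values across all target regions (reference regions are
#' never included).
#'
#' @param values named numeric vector or list, region -> value.
#' @param volumes named numeric vector or list, region -> volume (mL).
#' @param target_regions character vector of regions to average.
#' @return The weighted average `sum(v_i * vol_i) / sum(vol_i)`.
#' @export
composite_global <- function(values, volumes, target_regions) {
  values <- unlist(values); volumes <- unlist(volumes)
  pq_assert(length(target_regions) >= 1L, "need at least one target region")
  miss <- setdiff(target_regions, names(values))
  if (length(miss))
    pq_stop(paste("missing values for regions:", paste(miss, collapse = ", ")),
            "pq_key_error")
  miss <- setdiff(target_regions, names(volumes))
  if (length(miss))
    pq_stop(paste("missing volumes for regions:", paste(miss, collapse = ", ")),
            "pq_key_error")
  v <- values[target_regions]; w <- volumes[target_regions]
  pq_assert(all(is.finite(v)), "non-finite regional value")
  pq_assert(all(w > 0), "volumes must be positive")
  tot <- sum(w)
  if (tot <= 0) pq_stop("zero total volume", "pq_degenerate_error")
  sum(v * w) / tot
}

#' Create a scan session
#'
#' A scan session holds all regional TACs of one dynamic scan (sharing a
#' single frame schedule) plus acquisition metadata.
#'
#' @param subject_id,scan_id identifiers.
#' @param scan_role one of `"test"`, `"retest"`, `"baseline"`, `"followup"`.
#' @param tacs named list of [tac()] objects (names = region labels).
#' @param input_function optional [input_function()] (arterial data).
#' @param injected_dose_MBq,weight_kg optional positive scalars.
#' @param visual_status optional `"positive"` or `"negative"` visual read.
#' @param diagnosis optional `"CU"`, `"MCI"` or `"AD"`.
#' @param followup_years optional positive years since baseline (follow-up
#'   scans only).
#' @return An object of class `scan_session`.
#' @export
scan_session <- function(subject_id, scan_id, scan_role, tacs,
                         input_function = NULL,
                         injected_dose_MBq = NULL, weight_kg = NULL,
                         visual_status = NULL, diagnosis = NULL,
                         followup_years = NULL) {
  pq_assert(scan_role %in% c("test", "retest", "baseline", "followup"),
            "invalid scan_role")
  pq_assert(is.list(tacs) && length(tacs) >= 1L && !is.null(names(tacs)),
            "tacs must be a named list")
  pq_assert(all(vapply(tacs, inherits, logical(1), "tac")),
            "all elements of tacs must be tac objects")
  sched <- tacs[[1]]$schedule
  same <- vapply(tacs, function(x) {
    isTRUE(all.equal(x$schedule$start_times, sched$start_times)) &&
      isTRUE(all.equal(x$schedule$durations, sched$durations))
  }, logical(1))
  pq_assert(all(same), "all TACs must share one frame schedule")
  for (lab in names(tacs)) tacs[[lab]]$region_label <- lab
  if (!is.null(injected_dose_MBq))
    pq_assert(is_number(injected_dose_MBq) && injected_dose_MBq > 0,
              "injected_dose_MBq must be > 0")
  if (!is.null(weight_kg))
    pq_assert(is_number(weight_kg) && weight_kg > 0, "weight_kg must be > 0")
  if (!is.null(visual_status))
    pq_assert(visual_status %in% c("positive", "negative"),
              "visual_status must be 'positive' or 'negative'")
  if (!is.null(diagnosis))
    pq_assert(diagnosis %in% c("CU", "MCI", "AD"), "invalid diagnosis")
  if (!is.null(followup_years))
    pq_assert(is_number(followup_years) && followup_years > 0,
              "followup_years must be > 0")
  if (!is.null(input_function))
    stopifnot(inherits(input_function, "input_function"))
  structure(list(subject_id = as.character(subject_id),
                 scan_id = as.character(scan_id),
                 scan_role = scan_role, tacs = tacs,
                 input_function = input_function,
                 injected_dose_MBq = injected_dose_MBq,
                 weight_kg = weight_kg,
                 visual_status = visual_status,
                 diagnosis = diagnosis,
                 followup_years = followup_years,
                 schedule = sched),
            class = "scan_session")
}

#' Region labels of a session
#' @param session a [scan_session()].
#' @param targets_only drop the five reference-region labels.
#' @export
session_regions <- function(session, targets_only = FALSE) {
  labs <- names(session$tacs)
  if (targets_only) labs <- setdiff(labs, REFERENCE_REGIONS)
  labs
}

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a scan session from a TAC table and a metadata config
#'
#' The TAC table is UTF-8 delimited text (comma or tab, autodetected) with
#' columns `frame_start_min`, `frame_duration_min`, then one column per
#' region. Metadata is a YAML or JSON file (or an already-parsed list) with
#' `subject_id`, `scan_id`, `scan_role` and optionally `injected_dose_MBq`,
#' `weight_kg`, `visual_status`, `diagnosis`, `followup_years` and a
#' `volumes` map (region -> mL).
#'
#' @param tac_table_path path to the TAC table.
#' @param metadata path to the metadata config, or a named list.
#' @param blood_table_path optional path to a blood table understood by
#'   [read_blood_table()]; when given, the plasma input function is derived
#'   and attached.
#' @return A validated [scan_session()].
#' @export
read_session <- function(tac_table_path, metadata, blood_table_path = NULL) {
  pq_assert(file.exists(tac_table_path), "TAC table not found", "pq_io_error")
  df <- tryCatch(
    utils::read.table(tac_table_path, header = TRUE,
                      sep = sniff_delim(tac_table_path),
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) pq_stop(paste("cannot parse TAC table:",
                                      conditionMessage(e)), "pq_parse_error"))
  need <- c("frame_start_min", "frame_duration_min")
  if (!all(need %in% names(df)))
    pq_stop("TAC table must have frame_start_min and frame_duration_min columns",
            "pq_format_error")
  regions <- setdiff(names(df), need)
  if (!length(regions)) pq_stop("TAC table has no region columns", "pq_format_error")
  if (!all(vapply(df[regions], is.numeric, logical(1))))
    pq_stop("non-numeric activity values in TAC table", "pq_parse_error")
  sched <- frame_schedule(df$frame_start_min, df$frame_duration_min)

  meta <- if (is.character(metadata)) read_config(metadata) else metadata
  pq_assert(is.list(meta), "metadata must be a list or a config path")
  for (f in c("subject_id", "scan_id", "scan_role"))
    pq_assert(!is.null(meta[[f]]), paste("metadata missing", f), "pq_format_error")
  vols <- meta$volumes
  tacs <- lapply(regions, function(r)
    tac(sched, df[[r]], region_label = r, volume_ml = vols[[r]]))
  names(tacs) <- regions

  input <- NULL
  if (!is.null(blood_table_path)) {
    bl <- read_blood_table(blood_table_path)
    grid <- seq(0, scan_end(sched), by = 0.05)
    input <- derive_plasma_input(bl$samples, bl$corrections, grid)
  }
  scan_session(meta$subject_id, meta$scan_id, meta$scan_role, tacs,
               input_function = input,
               injected_dose_MBq = meta$injected_dose_MBq,
               weight_kg = meta$weight_kg,
               visual_status = meta$visual_status,
               diagnosis = meta$diagnosis,
               followup_years = meta$followup_years)
}

#' Write a scan session to a TAC table and metadata config
#'
#' Inverse of [read_session()]; values round-trip losslessly (full double
#' precision).
#'
#' @param session a [scan_session()].
#' @param tac_table_path output path for the TAC table (CSV).
#' @param metadata_path output path for the YAML metadata.
#' @export
write_session <- function(session, tac_table_path, metadata_path) {
  stopifnot(inherits(session, "scan_session"))
  df <- data.frame(frame_start_min = session$schedule$start_times,
                   frame_duration_min = session$schedule$durations,
                   check.names = FALSE)
  for (lab in names(session$tacs)) df[[lab]] <- session$tacs[[lab]]$values
  write_table_full(df, tac_table_path)
  vols <- lapply(session$tacs, function(x) x$volume_ml)
  vols <- vols[!vapply(vols, is.null, logical(1))]
  meta <- list(subject_id = session$subject_id, scan_id = session$scan_id,
               scan_role = session$scan_role,
               injected_dose_MBq = session$injected_dose_MBq,
               weight_kg = session$weight_kg,
               visual_status = session$visual_status,
               diagnosis = session$diagnosis,
               followup_years = session$followup_years,
               volumes = if (length(vols)) vols else NULL)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  yaml::write_yaml(meta, metadata_path, precision = 15)
  invisible(NULL)
}

# CSV writer preserving full double precision (%.17g round-trips doubles).
write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pq_stop(paste("cannot write", path), "pq_io_error")
  invisible(NULL)
}

read_config <- function(path) {
  pq_assert(file.exists(path), paste("config not found:", path), "pq_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Construct / validate a parameter table
#'
#' The parameter table is the pipeline's interchange object: one row per
#' (subject, scan, region, method, reference region) with the estimated
#' outcome value and an exclusion flag.
#'
#' @param df data frame with columns `subject_id, scan_id, region, method,
#'   reference_region, value, excluded`.
#' @return The validated data frame (class `parameter_table`).
#' @export
parameter_table <- function(df) {
  cols <- c("subject_id", "scan_id", "region", "method",
            "reference_region", "value", "excluded")
  pq_assert(all(cols %in% names(df)),
            paste("parameter table needs columns:", paste(cols, collapse = ", ")),
            "pq_format_error")
  df <- as.data.frame(df)[cols]
  df$excluded <- as.logical(df$excluded)
  key <- do.call(paste, c(df[c("subject_id", "scan_id", "region", "method",
                               "reference_region")], sep = "\r"))
  pq_assert(!anyDuplicated(key), "duplicate (subject, scan, region, method, reference) rows")
  bad <- !df$excluded & !is.finite(df$value)
  pq_assert(!any(bad), "non-finite value in non-excluded row")
  class(df) <- c("parameter_table", "data.frame")
  df
}

#' Write a parameter table to CSV
#' @param table a [parameter_table()].
#' @param path output path.
#' @export
write_parameter_table <- function(table, path) {
  table <- parameter_table(table)
  write_table_full(as.data.frame(table), path)
  invisible(NULL)
}

#' Read a parameter table from CSV
#' @param path path written by [write_parameter_table()].
#' @export
read_parameter_table <- function(path) {
  pq_assert(file.exists(path), "parameter table not found", "pq_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$excluded <- as.logical(df$excluded)
  } else {
    df$excluded <- logical(0)
    df$value <- numeric(0)
  }
  for (col in c("subject_id", "scan_id", "region", "method", "reference_region"))
    df[[col]] <- as.character(df[[col]])
  parameter_table(df)
}
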