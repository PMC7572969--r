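# End-to-end orchestration: quantify scan sessions into a parameter table,
# then compare reference regions. Mirrors the shell subcommands in
# inst/cli/pibquant.R (simulate / quantify / compare / demo).

#' Pipeline configuration
#'
#' @param methods quantification methods to run (subset of [DVR_METHODS]).
#' @param reference_regions reference regions to use.
#' @param t_star reference Logan linearization time (minutes).
#' @param weights fit weighting (`"duration"` or `"uniform"`).
#' @param n_starts,seed optimizer multi-start control.
#' @param bounds_2t4k,bounds_srtm parameter boxes; `bounds_srtm` may be a
#'   single list or a named per-reference-region list of lists.
#' @param compute_suv also emit reference-region/target SUV rows (methods
#'   `SUV_40_60` / `SUV_60_90`) when dose and weight are available.
#' @param composite_region label for the volume-weighted composite global
#'   cortical region (built from the target TACs when absent).
#' @param comparison a [comparison_config()].
#' @export
pipeline_config <- function(methods = DVR_METHODS,
                            reference_regions = REFERENCE_REGIONS,
                            t_star = 50, weights = "duration",
                            n_starts = 5, seed = 1,
                            bounds_2t4k = default_2t4k_bounds(),
                            bounds_srtm = default_srtm_bounds(),
                            compute_suv = TRUE,
                            composite_region = "global",
                            comparison = comparison_config()) {
  pq_assert(all(methods %in% DVR_METHODS), "unknown method requested",
            "pq_config_error")
  list(methods = methods, reference_regions = reference_regions,
       t_star = t_star, weights = weights, n_starts = n_starts, seed = seed,
       bounds_2t4k = bounds_2t4k, bounds_srtm = bounds_srtm,
       compute_suv = compute_suv, composite_region = composite_region,
       comparison = comparison)
}

srtm_bounds_for <- function(config, rr) {
  b <- config$bounds_srtm
  if (!is.null(b$lower)) return(b)        # single box for all RRs
  b[[rr]] %||% default_srtm_bounds()
}

# Volume-weighted composite TAC over the target regions.
composite_tac <- function(session, label = "global") {
  targets <- session_regions(session, targets_only = TRUE)
  vols <- vapply(targets, function(r)
    session$tacs[[r]]$volume_ml %||% NA_real_, numeric(1))
  if (anyNA(vols)) return(NULL)
  vals <- rep(0, length(session$schedule))
  for (r in targets) vals <- vals + session$tacs[[r]]$values * vols[[r]]
  tac(session$schedule, vals / sum(vols), label, volume_ml = sum(vols))
}

#' Quantify scan sessions into a parameter table
#'
#' Runs every requested method for every target region (plus the composite
#' global region) against every reference region. Plasma-input fits are
#' skipped with a logged reason for sessions without arterial data; SUV
#' rows are skipped without dose/weight.
#'
#' @param sessions list of [scan_session()]s.
#' @param config a [pipeline_config()].
#' @param verbose print per-scan progress to stderr.
#' @return A [parameter_table()]; skip reasons are in
#'   `attr(, "skip_log")`.
#' @export
run_quantify <- function(sessions, config = pipeline_config(),
                         verbose = FALSE) {
  if (inherits(sessions, "scan_session")) sessions <- list(sessions)
  rows <- list()
  skip_log <- character()
  say <- function(...) if (verbose) message(sprintf(...))
  for (s in sessions) {
    say("quantifying scan %s", s$scan_id)
    rrs <- intersect(config$reference_regions, names(s$tacs))
    pq_assert(length(rrs) >= 1L, "session has none of the requested reference regions",
              "pq_config_error")
    targets <- session_regions(s, targets_only = TRUE)
    comp_lab <- config$composite_region
    comp <- if (comp_lab %in% targets) NULL else composite_tac(s, comp_lab)
    quant_tacs <- s$tacs[targets]
    if (!is.null(comp)) quant_tacs[[comp_lab]] <- comp
    out_regions <- names(quant_tacs)

    add_row <- function(region, method, reference, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = s$subject_id, scan_id = s$scan_id, region = region,
        method = method, reference_region = reference, value = value,
        excluded = FALSE, stringsAsFactors = FALSE)
    }

    ## plasma-input model: one fit per region, DVR per reference region
    if ("DVR_PI" %in% config$methods) {
      if (is.null(s$input_function)) {
        skip_log <- c(skip_log, sprintf(
          "%s: DVR_PI skipped (no arterial input function)", s$scan_id))
      } else {
        fit_regions <- c(out_regions, rrs)
        vt <- vapply(fit_regions, function(r) {
          tt <- if (r %in% names(s$tacs)) s$tacs[[r]] else quant_tacs[[r]]
          fit_2t4k_vb(tt, s$input_function, weights = config$weights,
                      bounds = config$bounds_2t4k,
                      n_starts = config$n_starts,
                      seed = config$seed)$params$VT
        }, numeric(1))
        for (rr in rrs) for (reg in out_regions)
          add_row(reg, "DVR_PI", rr, dvr_from_vt(vt[[reg]], vt[[rr]]))
      }
    }

    for (rr in rrs) {
      ref_tac <- s$tacs[[rr]]
      if ("DVR_RLOGAN" %in% config$methods)
        for (reg in out_regions)
          add_row(reg, "DVR_RLOGAN", rr,
                  rlogan_dvr(quant_tacs[[reg]], ref_tac,
                             t_star = config$t_star)$DVR)
      if ("DVR_SRTM" %in% config$methods)
        for (reg in out_regions)
          add_row(reg, "DVR_SRTM", rr,
                  fit_srtm(quant_tacs[[reg]], ref_tac,
                           weights = config$weights,
                           bounds = srtm_bounds_for(config, rr),
                           n_starts = config$n_starts,
                           seed = config$seed)$params$DVR)
      for (wlab in c("40-60", "60-90")) {
        meth <- paste0("SUVR_", sub("-", "_", wlab))
        if (meth %in% config$methods) {
          w <- default_suv_windows()[[wlab]]
          for (reg in out_regions)
            add_row(reg, meth, rr, suvr_window(quant_tacs[[reg]], ref_tac, w))
        }
      }
    }

    ## absolute SUVs (reference regions + quantified regions)
    if (isTRUE(config$compute_suv)) {
      if (is.null(s$injected_dose_MBq) || is.null(s$weight_kg)) {
        skip_log <- c(skip_log, sprintf(
          "%s: SUV rows skipped (dose or weight unavailable)", s$scan_id))
      } else {
        for (wlab in c("40-60", "60-90")) {
          w <- default_suv_windows()[[wlab]]
          meth <- paste0("SUV_", sub("-", "_", wlab))
          for (reg in c(rrs, out_regions)) {
            tt <- if (reg %in% names(quant_tacs)) quant_tacs[[reg]] else s$tacs[[reg]]
            add_row(reg, meth, "none",
                    suv_window(tt, s$injected_dose_MBq, s$weight_kg, w))
          }
        }
      }
    }
  }
  tab <- parameter_table(do.call(rbind, c(rows, make.row.names = FALSE)))
  attr(tab, "skip_log") <- skip_log
  tab
}

#' Compare reference regions from parameter tables
#'
#' Thin wrapper over [build_comparison_report()] that optionally writes the
#' report files.
#'
#' @param params a [parameter_table()] (or path to one).
#' @param metadata data frame as from [sessions_metadata()] (or path to a
#'   CSV with the same columns).
#' @param config a [comparison_config()].
#' @param out_dir optional output directory for
#'   [write_comparison_report()].
#' @export
run_compare <- function(params, metadata, config = comparison_config(),
                        out_dir = NULL) {
  if (is.character(params)) params <- read_parameter_table(params)
  if (is.character(metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  report <- build_comparison_report(params, metadata, config)
  if (!is.null(out_dir)) write_comparison_report(report, out_dir)
  report
}

#' Run the packaged demo scenario end to end
#'
#' Simulates a small test-retest cohort and a longitudinal cohort, runs all
#' quantification methods, builds both comparison reports and writes every
#' artifact (parameter tables, truth tables, report JSON/CSVs) under
#' `out_dir`. Fully deterministic given `seed`.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_targets cortical targets per scan (kept small so the demo runs
#'   in minutes).
#' @param verbose print progress.
#' @return Invisibly, a list with both reports and parameter tables.
#' @export
run_demo <- function(out_dir, seed = 7, n_targets = 4, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trt_scen <- cohort_scenario(n_pos = 3, n_neg = 3, n_targets = n_targets,
                              seed = seed)
  long_scen <- cohort_scenario(n_pos = 5, n_neg = 4, n_targets = n_targets,
                               seed = seed + 1000L)
  trt <- generate_trt_cohort(trt_scen)
  lng <- generate_longitudinal_cohort(long_scen)
  cfg <- pipeline_config(seed = seed)

  ptrt <- run_quantify(trt$sessions, cfg, verbose = verbose)
  plng <- run_quantify(lng$sessions,
                       pipeline_config(methods = setdiff(DVR_METHODS, "DVR_PI"),
                                       seed = seed),
                       verbose = verbose)
  write_parameter_table(ptrt, file.path(out_dir, "params_trt.csv"))
  write_parameter_table(plng, file.path(out_dir, "params_long.csv"))
  write_table_full(trt$truth, file.path(out_dir, "truth_trt.csv"))
  write_table_full(lng$truth, file.path(out_dir, "truth_long.csv"))

  rep_trt <- run_compare(ptrt, sessions_metadata(trt$sessions),
                         out_dir = file.path(out_dir, "report_trt"))
  rep_lng <- run_compare(plng, sessions_metadata(lng$sessions),
                         out_dir = file.path(out_dir, "report_long"))
  invisible(list(report_trt = rep_trt, report_long = rep_lng,
                 params_trt = ptrt, params_long = plng))
}
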