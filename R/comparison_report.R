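# Report orchestration: applies MAD outlier exclusion, then computes every
# comparison section the available cohort supports (test-retest, agreement
# with the gold standard, longitudinal SUV stability, annual-change model
# selection, group discrimination).

#' Default comparison configuration
#'
#' @param gold_method,gold_reference the gold standard (plasma-input DVR
#'   with cerebellar grey matter).
#' @param composite_region label of the composite global cortical region.
#' @param mad_k MAD-outlier multiplier.
#' @param target_years follow-up standardization target (years).
#' @param bonferroni_stability family size for the paired-t stability tests
#'   (5 reference regions per window).
#' @param bonferroni_discrimination family size for the discrimination
#'   tests (5 reference regions x 4 reference-tissue methods).
#' @param agreement_role scan role whose data enter the agreement analyses.
#' @export
comparison_config <- function(gold_method = "DVR_PI", gold_reference = "GMCB",
                              composite_region = "global", mad_k = 3,
                              target_years = 2.6,
                              bonferroni_stability = 5,
                              bonferroni_discrimination = 20,
                              agreement_role = "test") {
  list(gold_method = gold_method, gold_reference = gold_reference,
       composite_region = composite_region, mad_k = mad_k,
       target_years = target_years,
       bonferroni_stability = bonferroni_stability,
       bonferroni_discrimination = bonferroni_discrimination,
       agreement_role = agreement_role)
}

#' Extract scan metadata from sessions
#'
#' @param sessions list of [scan_session()]s.
#' @return Data frame with one row per scan (subject, scan, role, visual
#'   status, diagnosis, follow-up years).
#' @export
sessions_metadata <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) data.frame(
    subject_id = s$subject_id, scan_id = s$scan_id, scan_role = s$scan_role,
    visual_status = s$visual_status %||% NA_character_,
    diagnosis = s$diagnosis %||% NA_character_,
    followup_years = s$followup_years %||% NA_real_,
    stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flag MAD outliers within each (region, method, reference_region) group
# across scans; returns the table plus an exclusion log.
apply_mad_exclusion <- function(params, k = 3) {
  params <- parameter_table(params)
  grp <- interaction(params$region, params$method, params$reference_region,
                     drop = TRUE)
  log_rows <- list()
  for (g in levels(grp)) {
    idx <- which(grp == g & !params$excluded)
    if (length(idx) < 3L) next
    mask <- mad_outliers(params$value[idx], k = k)
    if (any(mask)) {
      out <- idx[mask]
      params$excluded[out] <- TRUE
      log_rows[[g]] <- data.frame(
        subject_id = params$subject_id[out], scan_id = params$scan_id[out],
        region = params$region[out], method = params$method[out],
        reference_region = params$reference_region[out],
        value = params$value[out],
        group_median = stats::median(params$value[idx]),
        group_mad = 1.4826 * stats::median(abs(params$value[idx] -
                                                 stats::median(params$value[idx]))),
        stringsAsFactors = FALSE)
    }
  }
  list(params = params,
       log = if (length(log_rows)) do.call(rbind, c(log_rows, make.row.names = FALSE))
             else data.frame())
}

value_of <- function(params, scan, region, method, reference) {
  i <- which(params$scan_id == scan & params$region == region &
               params$method == method & params$reference_region == reference &
               !params$excluded)
  if (length(i) == 1L) params$value[i] else NA_real_
}

ratio_method_grid <- function(params) {
  unique(params[params$method %in% DVR_METHODS,
                c("method", "reference_region")])
}

#' Build the full reference-region comparison report
#'
#' Outlier exclusion is applied first (MAD criterion within each region x
#' method x reference-region group); each analysis section is then computed
#' whenever the cohort provides the scans it needs.
#'
#' @param params a [parameter_table()] (or data frame) covering all scans.
#' @param metadata data frame as from [sessions_metadata()].
#' @param config a [comparison_config()].
#' @return Object of class `comparison_report`: list with elements
#'   `exclusions`, `trt`, `agreement`, `bland_altman`, `stability`,
#'   `annual_change`, `discrimination`, `config`.
#' @export
build_comparison_report <- function(params, metadata,
                                    config = comparison_config()) {
  ex <- apply_mad_exclusion(params, k = config$mad_k)
  params <- ex$params
  comp <- config$composite_region
  grid <- ratio_method_grid(params)

  ## -- test-retest variability (composite region, per method x RR) --------
  trt <- NULL
  roles <- metadata$scan_role
  if (any(roles == "test") && any(roles == "retest")) {
    rows <- list()
    subjects <- intersect(metadata$subject_id[roles == "test"],
                          metadata$subject_id[roles == "retest"])
    for (i in seq_len(nrow(grid))) {
      meth <- grid$method[i]; rr <- grid$reference_region[i]
      for (s in subjects) {
        ts <- metadata$scan_id[metadata$subject_id == s & roles == "test"][1]
        rs <- metadata$scan_id[metadata$subject_id == s & roles == "retest"][1]
        Tv <- value_of(params, ts, comp, meth, rr)
        Rv <- value_of(params, rs, comp, meth, rr)
        if (is.na(Tv) || is.na(Rv)) next
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, reference_region = rr, subject_id = s,
          test = Tv, retest = Rv, trt_pct = trt_variability(Tv, Rv),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) trt <- do.call(rbind, rows)
  }

  ## -- agreement with the gold standard (regional, test scans) ------------
  agreement <- ba <- NULL
  gold_rows <- params$method == config$gold_method &
    params$reference_region == config$gold_reference & !params$excluded
  scans_agree <- metadata$scan_id[metadata$scan_role == config$agreement_role]
  if (any(gold_rows & params$scan_id %in% scans_agree)) {
    targets <- setdiff(unique(params$region), c(REFERENCE_REGIONS, comp))
    agr_rows <- list(); ba_rows <- list()
    for (i in seq_len(nrow(grid))) {
      meth <- grid$method[i]; rr <- grid$reference_region[i]
      g <- c(); v <- c()
      for (sc in scans_agree) for (reg in targets) {
        gv <- value_of(params, sc, reg, config$gold_method, config$gold_reference)
        mv <- value_of(params, sc, reg, meth, rr)
        if (!is.na(gv) && !is.na(mv)) { g <- c(g, gv); v <- c(v, mv) }
      }
      if (length(g) < 3L || stats::sd(g) == 0) next
      ag <- agreement_regression(g, v)
      bb <- bland_altman(g, v)
      agr_rows[[length(agr_rows) + 1L]] <- data.frame(
        method = meth, reference_region = rr, r = ag$r, slope = ag$slope,
        intercept = ag$intercept, n = ag$n, stringsAsFactors = FALSE)
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        method = meth, reference_region = rr, bias = bb$bias,
        loa_low = bb$loa_low, loa_high = bb$loa_high,
        trend_slope = bb$trend_slope, trend_intercept = bb$trend_intercept,
        n = bb$n, stringsAsFactors = FALSE)
    }
    if (length(agr_rows)) {
      agreement <- do.call(rbind, agr_rows)
      ba <- do.call(rbind, ba_rows)
    }
  }

  ## -- longitudinal SUV stability of the reference regions ----------------
  stability <- NULL
  has_long <- any(roles == "baseline") && any(roles == "followup")
  suv_methods <- intersect(unique(params$method), c("SUV_40_60", "SUV_60_90"))
  if (has_long && length(suv_methods)) {
    rows <- list()
    for (meth in suv_methods) {
      for (rr in intersect(unique(params$region), REFERENCE_REGIONS)) {
        bl <- c(); fu <- c()
        for (s in unique(metadata$subject_id)) {
          bs <- metadata$scan_id[metadata$subject_id == s & roles == "baseline"]
          fs <- metadata$scan_id[metadata$subject_id == s & roles == "followup"]
          if (!length(bs) || !length(fs)) next
          yrs <- metadata$followup_years[metadata$scan_id == fs[1]]
          bv <- value_of(params, bs[1], rr, meth, "none")
          fv <- value_of(params, fs[1], rr, meth, "none")
          if (is.na(bv) || is.na(fv) || is.na(yrs)) next
          bl <- c(bl, bv)
          fu <- c(fu, standardize_followup(bv, fv, yrs, config$target_years))
        }
        if (length(bl) < 3L) next
        tt <- tryCatch(paired_t_test(bl, fu), pq_error = function(e) NULL)
        if (is.null(tt)) next
        rows[[length(rows) + 1L]] <- data.frame(
          window = sub("SUV_", "", meth), region = rr, n = length(bl),
          mean_baseline = mean(bl), mean_followup_std = mean(fu),
          t = tt$t, p_value = tt$p_value, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      stability <- do.call(rbind, rows)
      stability$p_adjusted <- NA_real_
      for (wdw in unique(stability$window)) {
        i <- stability$window == wdw
        stability$p_adjusted[i] <-
          bonferroni_adjust(stability$p_value[i], config$bonferroni_stability)
      }
    }
  }

  ## -- annual change vs baseline burden, linear vs quadratic --------------
  annual <- NULL
  if (has_long) {
    rows <- list()
    for (i in seq_len(nrow(grid))) {
      meth <- grid$method[i]; rr <- grid$reference_region[i]
      xb <- c(); yc <- c()
      for (s in unique(metadata$subject_id)) {
        bs <- metadata$scan_id[metadata$subject_id == s & roles == "baseline"]
        fs <- metadata$scan_id[metadata$subject_id == s & roles == "followup"]
        if (!length(bs) || !length(fs)) next
        yrs <- metadata$followup_years[metadata$scan_id == fs[1]]
        bv <- value_of(params, bs[1], comp, meth, rr)
        fv <- value_of(params, fs[1], comp, meth, rr)
        if (is.na(bv) || is.na(fv) || is.na(yrs) || bv == 0) next
        xb <- c(xb, bv)
        yc <- c(yc, annual_percent_change(bv, fv, yrs))
      }
      if (length(xb) < 4L || stats::sd(xb) == 0) next
      mc <- fit_linear_quadratic_aic(xb, yc)
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, reference_region = rr, n = mc$n,
        aic_linear = mc$aic_linear, aic_quadratic = mc$aic_quadratic,
        delta_aic = mc$delta_aic, preferred = mc$preferred,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) annual <- do.call(rbind, rows)
  }

  ## -- discrimination between visually Abeta+ and Abeta- scans ------------
  discrimination <- NULL
  vs <- metadata$visual_status
  if (any(!is.na(vs))) {
    # subjects with a stable visual assessment across their available scans
    stable <- vapply(split(vs, metadata$subject_id),
                     function(v) all(!is.na(v)) && length(unique(v)) == 1L,
                     logical(1))
    keep <- metadata$subject_id %in% names(stable)[stable]
    rows <- list()
    for (i in seq_len(nrow(grid))) {
      meth <- grid$method[i]; rr <- grid$reference_region[i]
      neg <- c(); pos <- c()
      for (j in which(keep)) {
        v <- value_of(params, metadata$scan_id[j], comp, meth, rr)
        if (is.na(v)) next
        if (vs[j] == "negative") neg <- c(neg, v) else pos <- c(pos, v)
      }
      if (length(neg) < 2L || length(pos) < 2L) next
      mw <- mann_whitney_u(neg, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, reference_region = rr,
        n_negative = length(neg), n_positive = length(pos),
        u_statistic = mw$U, p_value = mw$p_value,
        hodges_lehmann = hodges_lehmann(neg, pos),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      discrimination <- do.call(rbind, rows)
      discrimination$p_adjusted <-
        bonferroni_adjust(discrimination$p_value,
                          config$bonferroni_discrimination)
    }
  }

  structure(list(exclusions = ex$log, trt = trt, agreement = agreement,
                 bland_altman = ba, stability = stability,
                 annual_change = annual, discrimination = discrimination,
                 config = config),
            class = "comparison_report")
}

#' Summarize TRT variability per method x reference region
#' @param report a [build_comparison_report()] result.
#' @return Data frame with mean/median/max TRT percent per cell, or NULL.
#' @export
trt_summary <- function(report) {
  if (is.null(report$trt)) return(NULL)
  agg <- split(report$trt$trt_pct,
               interaction(report$trt$method, report$trt$reference_region,
                           drop = TRUE))
  keys <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  data.frame(method = keys[, 1], reference_region = keys[, 2],
             n = vapply(agg, length, integer(1)),
             mean_pct = vapply(agg, mean, numeric(1)),
             median_pct = vapply(agg, stats::median, numeric(1)),
             max_pct = vapply(agg, max, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a comparison report to disk
#'
#' Serializes the full report as JSON and each table section as CSV.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_comparison_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (section in c("trt", "agreement", "bland_altman", "stability",
                    "annual_change", "discrimination")) {
    tab <- report[[section]]
    if (!is.null(tab) && nrow(tab))
      write_table_full(tab, file.path(dir, paste0(section, ".csv")))
  }
  json_path <- file.path(dir, "report.json")
  out <- report
  class(out) <- NULL
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(json_path)
}

#' Bland-Altman plot
#'
#' @param gold,method paired values.
#' @param main plot title.
#' @export
plot_bland_altman <- function(gold, method, main = "Bland-Altman") {
  b <- bland_altman(gold, method)
  m <- (gold + method) / 2
  d <- method - gold
  plot(m, d, xlab = "Mean of method and gold standard",
       ylab = "Difference (method - gold)", main = main, pch = 19)
  graphics::abline(h = c(b$bias, b$loa_low, b$loa_high),
                   lty = c(1, 2, 2), col = "grey40")
  graphics::abline(b$trend_intercept, b$trend_slope, col = "red")
  invisible(b)
}
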