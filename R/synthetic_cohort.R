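# Synthetic dynamic-PiB cohort generator.
#
# Generates 90-min dynamic scans with one arterial input, ~19 cortical
# target regions and the five candidate reference regions, with distinct
# grey- and white-matter kinetics, test-retest replicates and a ~2.6-year
# longitudinal follow-up with optional white-matter SUV drift. Every region
# is simulated from known micro-parameters, so a sidecar truth table
# (generating VT and DVR) accompanies each cohort and the whole pipeline
# can be validated without patient data.

#' Default 20-frame, 90-min dynamic framing scheme
#'
#' 4 x 0.25, 4 x 1, 2 x 2.5, 4 x 5 and 6 x 10 min frames. This is a
#' plausible dynamic-PiB framing declared by the package, not a reproduction
#' of any scanner protocol.
#' @export
default_frame_schedule <- function() {
  durs <- c(rep(0.25, 4), rep(1, 4), rep(2.5, 2), rep(5, 4), rep(10, 6))
  frame_schedule(cumsum(c(0, durs[-length(durs)])), durs)
}

#' Feng-type arterial plasma curve
#'
#' `C_p(t') = (A1*t' - A2 - A3) e^{l1 t'} + A2 e^{l2 t'} + A3 e^{l3 t'}`
#' for `t' = t - delay > 0`, else 0. The default parameter set is the
#' classic tri-exponential arterial surrogate scaled to kBq/mL.
#'
#' @param grid time grid (minutes).
#' @param A1,A2,A3 amplitudes; `A1` in kBq/mL/min, others kBq/mL.
#' @param l1,l2,l3 exponents (min^-1), `l1 < l2 < l3 < 0`.
#' @param delay appearance delay (minutes, >= 0).
#' @return Plasma curve values on `grid`.
#' @export
feng_plasma_input <- function(grid, A1 = 340, A2 = 8.75, A3 = 8.32,
                              l1 = -4.134, l2 = -0.1191, l3 = -0.01043,
                              delay = 0) {
  pq_assert(l1 < l2 && l2 < l3 && l3 < 0, "need l1 < l2 < l3 < 0")
  pq_assert(delay >= 0, "delay must be >= 0")
  tp <- grid - delay
  cp <- ifelse(tp > 0,
               (A1 * tp - A2 - A3) * exp(l1 * tp) +
                 A2 * exp(l2 * tp) + A3 * exp(l3 * tp),
               0)
  if (any(cp < -1e-9))
    pq_stop("Feng parameters yield negative plasma concentrations",
            "pq_validation_error")
  pmax(cp, 0)
}

#' Default blood correction models
#'
#' Plasma-to-whole-blood ratio rising linearly 1.0 -> 1.2 over 90 min and a
#' Hill-type parent fraction falling from 1 to ~0.1 at 90 min. Declared
#' simulation assumptions (PiB metabolite data are not modelled on any
#' published fit).
#' @export
default_corrections <- function() {
  correction_model(
    plasma_to_wholeblood = function(t) 1 + 0.2 * pmin(t, 90) / 90,
    parent_fraction = function(t) 1 / (1 + (pmax(t, 0) / 20)^1.5))
}

#' Build the synthetic arterial input
#'
#' The Feng curve is taken as total plasma activity; parent plasma is
#' `total * parent_fraction` and whole blood is `total / ratio`, so
#' [derive_plasma_input()] applied to the emitted whole-blood samples and
#' corrections recovers the parent plasma curve exactly.
#'
#' @param t_end scan end (minutes).
#' @param dt grid spacing (minutes).
#' @param corrections a [correction_model()].
#' @param ... passed to [feng_plasma_input()].
#' @return List with `input` (an [input_function()]), `corrections`, and
#'   `samples` (whole-blood sample table for serialization).
#' @export
make_synthetic_input <- function(t_end = 90, dt = 0.05,
                                 corrections = default_corrections(), ...) {
  grid <- seq(0, t_end, by = dt)
  total <- feng_plasma_input(grid, ...)
  pf <- corrections$parent_fraction(grid)
  ratio <- corrections$plasma_to_wholeblood(grid)
  wb <- total / ratio
  parent <- total * pf
  list(input = input_function(grid, parent, wb),
       corrections = corrections,
       samples = data.frame(time_min = grid, whole_blood_kBq_ml = wb,
                            plasma_to_wb_ratio = ratio,
                            parent_fraction = pf))
}

#' Region kinetics profile
#'
#' @param region_label region name.
#' @param K1,k2,k3,k4,Vb 2T4k_Vb micro-parameters (a one-tissue profile has
#'   `k3 = 0`).
#' @param tissue_class `"grey"`, `"white"` or `"mixed"`.
#' @param volume_ml region volume.
#' @param mixture optional list of `list(params = kinetic_params_2t4k,
#'   weight = w)` components; when given, the region TAC is the
#'   volume-weighted mixture of the component curves.
#' @return Object of class `region_profile`.
#' @export
region_profile <- function(region_label, K1 = NULL, k2 = NULL, k3 = 0,
                           k4 = 0.05, Vb = 0.05, tissue_class = "grey",
                           volume_ml = 10, mixture = NULL) {
  pq_assert(tissue_class %in% c("grey", "white", "mixed"),
            "invalid tissue_class")
  params <- NULL
  if (is.null(mixture)) {
    params <- kinetic_params_2t4k(K1, k2, k3, k4, Vb)
  } else {
    ws <- vapply(mixture, `[[`, numeric(1), "weight")
    pq_assert(abs(sum(ws) - 1) < 1e-9, "mixture weights must sum to 1")
  }
  structure(list(region_label = region_label, params = params,
                 tissue_class = tissue_class, volume_ml = volume_ml,
                 mixture = mixture),
            class = "region_profile")
}

profile_vt <- function(profile) {
  if (is.null(profile$mixture)) return(profile$params$VT)
  sum(vapply(profile$mixture,
             function(m) m$weight * m$params$VT, numeric(1)))
}

#' The 19 cortical target-region labels used by default
#' @export
default_target_labels <- function() {
  c("medial_anterior_temporal", "lateral_anterior_temporal",
    "posterior_temporal", "superior_temporal", "middle_temporal",
    "inferior_temporal", "fusiform", "parahippocampal_ambient",
    "anterior_cingulate", "posterior_cingulate", "middle_frontal",
    "orbitofrontal", "gyrus_rectus", "inferior_frontal", "superior_frontal",
    "precentral", "postcentral", "superior_parietal", "lateral_parietal")
}

# Fixed per-region volume and DVR-spread factors (deterministic; part of
# the declared scenario, not of the random draw).
target_region_factors <- function(labels) {
  n <- length(labels)
  i <- seq_len(n)
  list(volume = 8 + 6 * ((i * 7) %% n) / max(n - 1, 1),
       spread = 0.92 + 0.16 * ((i * 5) %% n) / max(n - 1, 1))
}

#' Default reference-region kinetic profiles
#'
#' Cerebellar grey matter is one-tissue-like with VT = 2.0; white-matter
#' regions have lower delivery, slower clearance and higher VT (2.8-3.5),
#' which mechanistically produces the slower late-time decline and the
#' under-estimation (slope < 1) of white-matter-referenced methods. The
#' whole cerebellum is a 70/30 grey/white TAC mixture and the whole
#' brainstem a 25/75 grey/white mixture.
#' @export
default_reference_profiles <- function() {
  gm <- kinetic_params_2t4k(0.30, 0.15, 0, 0.05, 0.03)       # VT 2.0
  cbwm <- kinetic_params_2t4k(0.10, 0.035, 0, 0.05, 0.02)    # VT 2.857
  bsgm <- kinetic_params_2t4k(0.25, 0.125, 0, 0.05, 0.03)    # VT 2.0
  bswm <- kinetic_params_2t4k(0.10, 0.036, 0, 0.05, 0.02)    # VT 2.778
  list(
    GMCB = region_profile("GMCB", 0.30, 0.15, 0, 0.05, 0.03,
                          tissue_class = "grey", volume_ml = 60),
    WCB = region_profile("WCB", tissue_class = "mixed", volume_ml = 130,
                         mixture = list(list(params = gm, weight = 0.7),
                                        list(params = cbwm, weight = 0.3))),
    WMBS = region_profile("WMBS", 0.10, 0.036, 0, 0.05, 0.02,
                          tissue_class = "white", volume_ml = 18),
    WBS = region_profile("WBS", tissue_class = "mixed", volume_ml = 30,
                         mixture = list(list(params = bsgm, weight = 0.25),
                                        list(params = bswm, weight = 0.75))),
    WMES = region_profile("WMES", 0.105, 0.030, 0, 0.05, 0.02,
                          tissue_class = "white", volume_ml = 80))
}

# Target profile for a wanted DVR (relative to the GMCB VT of 2.0): burden
# goes into k3 when DVR > 1, into faster clearance when DVR < 1.
target_profile_for_dvr <- function(label, dvr, volume_ml, k4 = 0.1) {
  if (dvr >= 1) {
    region_profile(label, 0.30, 0.15, k4 * (dvr - 1), k4, 0.03,
                   tissue_class = "grey", volume_ml = volume_ml)
  } else {
    region_profile(label, 0.30, 0.15 / dvr, 0, k4, 0.03,
                   tissue_class = "grey", volume_ml = volume_ml)
  }
}

#' Build the region profile set for one synthetic subject
#'
#' @param global_dvr the subject's global target DVR (vs cerebellar grey).
#' @param n_targets number of cortical target regions (up to 19).
#' @return Named list of [region_profile()]s: targets plus the five
#'   reference regions.
#' @export
subject_profiles <- function(global_dvr, n_targets = 19) {
  labels <- default_target_labels()[seq_len(min(n_targets, 19))]
  fac <- target_region_factors(labels)
  targets <- lapply(seq_along(labels), function(i) {
    dvr_i <- max(global_dvr * fac$spread[i], 0.8)
    target_profile_for_dvr(labels[i], dvr_i, fac$volume[i])
  })
  names(targets) <- labels
  c(targets, default_reference_profiles())
}

#' Add frame-duration-scaled Gaussian noise to a TAC
#'
#' `value_i + e_i` with
#' `e_i ~ Normal(0, level * max(value_i, floor) / sqrt(duration_i))`;
#' a surrogate for reconstruction/count noise. Level 0 returns the TAC
#' unchanged; results are deterministic given `seed`.
#'
#' @param x a [tac()].
#' @param level fractional noise SD at unit frame duration (>= 0).
#' @param seed integer seed.
#' @param floor lower bound (kBq/mL) on the amplitude entering the SD.
#' @export
add_tac_noise <- function(x, level, seed, floor = 0.01) {
  stopifnot(inherits(x, "tac"))
  pq_assert(level >= 0, "noise level must be >= 0")
  if (level == 0) return(x)
  sd_i <- level * pmax(x$values, floor) / sqrt(x$schedule$durations)
  eps <- local({
    set.seed(as.integer(seed %% .Machine$integer.max))
    stats::rnorm(length(sd_i), 0, sd_i)
  })
  tac(x$schedule, x$values + eps, x$region_label, x$volume_ml)
}

simulate_profile_tac <- function(profile, input, schedule) {
  if (is.null(profile$mixture)) {
    simulate_2t4k(profile$params, input, schedule,
                  region_label = profile$region_label,
                  volume_ml = profile$volume_ml)
  } else {
    parts <- lapply(profile$mixture, function(m)
      simulate_2t4k(m$params, input, schedule)$values * m$weight)
    tac(schedule, Reduce(`+`, parts), profile$region_label,
        volume_ml = profile$volume_ml)
  }
}

#' Generate one synthetic scan
#'
#' Every region is simulated from its kinetic profile (blood-volume term
#' included) and noise is added per region; the generating truth (VT and
#' DVR vs cerebellar grey matter) is returned as a sidecar table.
#'
#' @param profiles named list of [region_profile()]s, including the five
#'   reference regions.
#' @param input an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param noise_level fractional noise SD at unit duration.
#' @param seed integer seed for the noise.
#' @param subject_id,scan_id,scan_role,dose_MBq,weight_kg,visual_status,diagnosis,followup_years
#'   session metadata.
#' @return List with `session` ([scan_session()]) and `truth` (data frame:
#'   region, tissue_class, true_VT, true_DVR).
#' @export
generate_scan <- function(profiles, input, schedule, noise_level = 0,
                          seed = 1, subject_id = "S1", scan_id = "S1_scan",
                          scan_role = "test", dose_MBq = 370,
                          weight_kg = 75, visual_status = NULL,
                          diagnosis = NULL, followup_years = NULL) {
  pq_assert(all(REFERENCE_REGIONS %in% names(profiles)),
            "profiles must include all five reference regions",
            "pq_config_error")
  pq_assert(length(setdiff(names(profiles), REFERENCE_REGIONS)) >= 1L,
            "profiles must include at least one target region",
            "pq_config_error")
  tacs <- lapply(profiles, simulate_profile_tac, input = input,
                 schedule = schedule)
  if (noise_level > 0)
    tacs <- lapply(seq_along(tacs), function(i)
      add_tac_noise(tacs[[i]], noise_level,
                    (as.numeric(seed) * 131 + i) %% 2147483647))
  names(tacs) <- names(profiles)
  vt <- vapply(profiles, profile_vt, numeric(1))
  truth <- data.frame(subject_id = subject_id, scan_id = scan_id,
                      region = names(profiles),
                      tissue_class = vapply(profiles, `[[`, character(1),
                                            "tissue_class"),
                      true_VT = unname(vt),
                      true_DVR = unname(vt / vt[["GMCB"]]),
                      stringsAsFactors = FALSE)
  session <- scan_session(subject_id, scan_id, scan_role, tacs,
                          input_function = input,
                          injected_dose_MBq = dose_MBq, weight_kg = weight_kg,
                          visual_status = visual_status, diagnosis = diagnosis,
                          followup_years = followup_years)
  list(session = session, truth = truth)
}

#' Cohort scenario
#'
#' Defines the statistical structure of a synthetic cohort: group sizes,
#' target-DVR ranges for visually Abeta-positive (1.8-2.5) and -negative
#' (0.95-1.2) subjects, the noise level, the longitudinal design (follow-up
#' interval 2.6 +/- 0.45 years, truncated to 1.9-4.0; inverted-U annual
#' accumulation peaking at mid-range burden) and the optional white-matter
#' SUV drift of the brainstem regions.
#'
#' @param n_pos,n_neg subjects per group.
#' @param dvr_range_pos,dvr_range_neg global-DVR ranges per group.
#' @param noise_level fractional TAC noise SD at unit duration.
#' @param n_targets cortical target regions per scan (<= 19).
#' @param followup_mean_years,followup_sd_years,followup_range follow-up
#'   interval distribution (truncated normal).
#' @param accumulation_rmax peak annual percentage change (%/year) of the
#'   inverted-U accumulation function.
#' @param accumulation_range DVR interval outside which accumulation is 0.
#' @param wm_drift_pct_per_year multiplicative annual change (%) applied to
#'   the delivery (K1) of the brainstem regions at follow-up; their VT and
#'   SUV drift down together.
#' @param seed master seed; all randomness derives from it.
#' @export
cohort_scenario <- function(n_pos = 7, n_neg = 6,
                            dvr_range_pos = c(1.8, 2.5),
                            dvr_range_neg = c(0.95, 1.2),
                            noise_level = 0.05, n_targets = 19,
                            followup_mean_years = 2.525,
                            followup_sd_years = 0.45,
                            followup_range = c(1.92, 4.0),
                            accumulation_rmax = 6,
                            accumulation_range = c(1.0, 3.0),
                            wm_drift_pct_per_year = -2,
                            seed = 1) {
  pq_assert(n_pos >= 1 && n_neg >= 1, "group sizes must be >= 1")
  pq_assert(noise_level >= 0, "noise level must be >= 0")
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 dvr_range_pos = dvr_range_pos, dvr_range_neg = dvr_range_neg,
                 noise_level = noise_level, n_targets = n_targets,
                 followup_mean_years = followup_mean_years,
                 followup_sd_years = followup_sd_years,
                 followup_range = followup_range,
                 accumulation_rmax = accumulation_rmax,
                 accumulation_range = accumulation_range,
                 wm_drift_pct_per_year = wm_drift_pct_per_year,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

# Inverted-U annual percentage change as a function of baseline global DVR.
accumulation_rate <- function(dvr, rmax, range) {
  lo <- range[1]; hi <- range[2]
  pmax(rmax * 4 * (dvr - lo) * (hi - dvr) / (hi - lo)^2, 0)
}

rtruncnorm1 <- function(mean, sd, range) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  mean
}

subject_draws <- function(scenario) {
  n <- scenario$n_pos + scenario$n_neg
  status <- rep(c("positive", "negative"), c(scenario$n_pos, scenario$n_neg))
  rng <- lapply(status, function(s)
    if (s == "positive") scenario$dvr_range_pos else scenario$dvr_range_neg)
  data.frame(subject_id = sprintf("sub%02d", seq_len(n)),
             visual_status = status,
             global_dvr = vapply(rng, function(r) stats::runif(1, r[1], r[2]),
                                 numeric(1)),
             dose_MBq = stats::rnorm(n, 370, 25),
             weight_kg = stats::rnorm(n, 76, 10),
             noise_seed = sample.int(2^30, n),
             stringsAsFactors = FALSE)
}

#' Generate a test-retest cohort
#'
#' Per subject, two same-day scans simulated from identical generating
#' parameters with independent noise; arterial data are attached to both.
#'
#' @param scenario a [cohort_scenario()].
#' @return List with `sessions` (named list of [scan_session()]s), `truth`
#'   (row-bound sidecar tables) and `blood` (whole-blood sample table).
#' @export
generate_trt_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(scenario$seed)
  subj <- subject_draws(scenario)
  syn <- make_synthetic_input()
  schedule <- default_frame_schedule()
  sessions <- list(); truth <- list()
  for (i in seq_len(nrow(subj))) {
    prof <- subject_profiles(subj$global_dvr[i], scenario$n_targets)
    for (k in 1:2) {
      role <- c("test", "retest")[k]
      sid <- paste0(subj$subject_id[i], "_", role)
      g <- generate_scan(prof, syn$input, schedule,
                         noise_level = scenario$noise_level,
                         seed = subj$noise_seed[i] + k,
                         subject_id = subj$subject_id[i], scan_id = sid,
                         scan_role = role, dose_MBq = subj$dose_MBq[i],
                         weight_kg = subj$weight_kg[i],
                         visual_status = subj$visual_status[i])
      sessions[[sid]] <- g$session
      truth[[sid]] <- g$truth
    }
  }
  list(sessions = sessions,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       blood = syn$samples)
}

drifted_profile <- function(profile, factor) {
  scale_params <- function(p)
    kinetic_params_2t4k(p$K1 * factor, p$k2, p$k3, p$k4, p$Vb)
  if (is.null(profile$mixture)) {
    profile$params <- scale_params(profile$params)
  } else {
    profile$mixture <- lapply(profile$mixture, function(m) {
      m$params <- scale_params(m$params); m
    })
  }
  profile
}

#' Generate a longitudinal cohort
#'
#' Per subject, a baseline and one follow-up scan. The follow-up interval is
#' a truncated normal draw; the target k3 evolves with an inverted-U annual
#' accumulation function of baseline burden; the brainstem white-matter
#' regions optionally drift in delivery (K1 scaled down annually, so their
#' VT and SUV fall together while every other region is stable). Dose and
#' weight are attached so SUVs are computable.
#'
#' @param scenario a [cohort_scenario()].
#' @return As [generate_trt_cohort()].
#' @export
generate_longitudinal_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(scenario$seed + 1L)
  subj <- subject_draws(scenario)
  syn <- make_synthetic_input()
  schedule <- default_frame_schedule()
  sessions <- list(); truth <- list()
  for (i in seq_len(nrow(subj))) {
    yrs <- rtruncnorm1(scenario$followup_mean_years,
                       scenario$followup_sd_years, scenario$followup_range)
    dvr_bl <- subj$global_dvr[i]
    rate <- accumulation_rate(dvr_bl, scenario$accumulation_rmax,
                              scenario$accumulation_range)
    dvr_fu <- dvr_bl * (1 + rate * yrs / 100)
    drift_f <- (1 + scenario$wm_drift_pct_per_year / 100)^yrs
    prof_bl <- subject_profiles(dvr_bl, scenario$n_targets)
    prof_fu <- subject_profiles(dvr_fu, scenario$n_targets)
    for (rr in c("WMBS", "WBS"))
      prof_fu[[rr]] <- drifted_profile(prof_fu[[rr]], drift_f)
    for (k in 1:2) {
      role <- c("baseline", "followup")[k]
      sid <- paste0(subj$subject_id[i], "_", role)
      g <- generate_scan(if (k == 1) prof_bl else prof_fu,
                         syn$input, schedule,
                         noise_level = scenario$noise_level,
                         seed = subj$noise_seed[i] + 7L * k,
                         subject_id = subj$subject_id[i], scan_id = sid,
                         scan_role = role, dose_MBq = subj$dose_MBq[i],
                         weight_kg = subj$weight_kg[i],
                         visual_status = subj$visual_status[i],
                         followup_years = if (k == 2) yrs else NULL)
      sessions[[sid]] <- g$session
      truth[[sid]] <- g$truth
    }
  }
  list(sessions = sessions,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       blood = syn$samples)
}

#' Write a cohort to a directory
#'
#' Emits, per scan, `<scan_id>_tacs.csv` and `<scan_id>_meta.yaml`, plus a
#' shared `blood.csv` and the `truth.csv` sidecar.
#'
#' @param cohort result of a cohort generator.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$sessions)) {
    s <- cohort$sessions[[sid]]
    write_session(s, file.path(dir, paste0(sid, "_tacs.csv")),
                  file.path(dir, paste0(sid, "_meta.yaml")))
  }
  write_blood_table(cohort$blood, file.path(dir, "blood.csv"))
  write_table_full(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @param attach_blood derive and attach the plasma input to every session.
#' @return List with `sessions` and (if present) `truth`.
#' @export
read_cohort <- function(dir, attach_blood = TRUE) {
  metas <- sort(list.files(dir, pattern = "_meta\\.yaml$", full.names = TRUE))
  pq_assert(length(metas) >= 1L, "no sessions found in directory", "pq_io_error")
  blood <- file.path(dir, "blood.csv")
  blood <- if (attach_blood && file.exists(blood)) blood else NULL
  sessions <- lapply(metas, function(mp) {
    tp <- sub("_meta\\.yaml$", "_tacs.csv", mp)
    read_session(tp, mp, blood_table_path = blood)
  })
  names(sessions) <- vapply(sessions, `[[`, character(1), "scan_id")
  tr <- file.path(dir, "truth.csv")
  list(sessions = sessions,
       truth = if (file.exists(tr)) utils::read.csv(tr, stringsAsFactors = FALSE)
               else NULL)
}
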