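test_that("Feng plasma curve is zero before the delay and single-peaked after", {
  grid <- seq(0, 90, 0.05)
  cp <- feng_plasma_input(grid, delay = 0.7)
  expect_true(all(cp[grid <= 0.7] == 0))
  expect_true(all(cp >= 0))
  pk <- which.max(cp)
  expect_gt(grid[pk], 0.7)
  expect_lt(grid[pk], 3)            # early peak
  expect_true(all(diff(cp[pk:length(cp)]) <= 1e-9))  # monotone decline after
  expect_error(feng_plasma_input(grid, l1 = -0.1, l2 = -0.2, l3 = -0.3),
               class = "pq_validation_error")
})

test_that("synthetic blood data round-trip through derive_plasma_input", {
  syn <- fx_input()
  rebuilt <- derive_plasma_input(syn$samples, syn$corrections,
                                 syn$input$times)
  expect_equal(rebuilt$plasma_parent, syn$input$plasma_parent,
               tolerance = 1e-9)
  expect_equal(rebuilt$whole_blood, syn$input$whole_blood, tolerance = 1e-9)
})

test_that("TAC noise is seed-deterministic and scales as specified", {
  x <- fx_gmcb()
  expect_identical(add_tac_noise(x, 0, seed = 1)$values, x$values)
  n1 <- add_tac_noise(x, 0.05, seed = 42)
  n2 <- add_tac_noise(x, 0.05, seed = 42)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_tac_noise(x, 0.05, seed = 43)$values, n1$values))
  # Monte-Carlo SD per frame matches level * max(v, floor) / sqrt(dur)
  reps <- vapply(1:1000, function(s)
    add_tac_noise(x, 0.1, seed = s)$values - x$values,
    numeric(length(x$values)))
  emp_sd <- apply(reps, 1, sd)
  expected <- 0.1 * pmax(x$values, 0.01) / sqrt(x$schedule$durations)
  expect_true(all(abs(emp_sd / expected - 1) < 0.15))
  expect_equal(median(abs(emp_sd / expected - 1)), 0, tolerance = 0.05)
})

test_that("generate_scan stores truth consistent with refits and shape ordering", {
  syn <- fx_input()
  prof <- subject_profiles(2.0, n_targets = 2)
  g <- generate_scan(prof, syn$input, fx_schedule(), noise_level = 0, seed = 1)
  expect_setequal(g$truth$region, names(prof))
  expect_equal(g$truth$true_DVR[g$truth$region == "GMCB"], 1.0)
  # noise-free fit recovers sidecar VT (one target spot-checked)
  fit <- fit_2t4k_vb(g$session$tacs[[1]], syn$input)
  expect_lt(abs(fit$params$VT / g$truth$true_VT[1] - 1), 0.01)
  # white-matter reference TACs decline more slowly late than GMCB
  late_decline <- function(tt) {
    v <- tt$values
    (v[15] - v[20]) / v[15]   # mid-times 52.5 and 85 min
  }
  expect_gt(late_decline(g$session$tacs$GMCB),
            late_decline(g$session$tacs$WMBS))
  expect_gt(late_decline(g$session$tacs$GMCB),
            late_decline(g$session$tacs$WMES))
  # missing reference region is a configuration error
  expect_error(generate_scan(prof[setdiff(names(prof), "WMES")], syn$input,
                             fx_schedule()),
               class = "pq_config_error")
})

test_that("cohort generators are byte-identical under a fixed seed", {
  scen <- cohort_scenario(n_pos = 2, n_neg = 2, n_targets = 2, seed = 11)
  c1 <- generate_trt_cohort(scen)
  c2 <- generate_trt_cohort(scen)
  expect_identical(c1$truth, c2$truth)
  for (sid in names(c1$sessions))
    for (r in names(c1$sessions[[sid]]$tacs))
      expect_identical(c1$sessions[[sid]]$tacs[[r]]$values,
                       c2$sessions[[sid]]$tacs[[r]]$values)
  # and on-disk artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  l1 <- generate_longitudinal_cohort(scen)
  l2 <- generate_longitudinal_cohort(scen)
  expect_identical(l1$truth, l2$truth)
})

test_that("test-retest pairs share generating parameters but not noise", {
  scen <- cohort_scenario(n_pos = 1, n_neg = 1, n_targets = 2, seed = 5)
  co <- generate_trt_cohort(scen)
  expect_length(co$sessions, 4L)
  tr <- co$truth
  for (s in unique(tr$subject_id)) {
    pair <- tr[tr$subject_id == s, ]
    tst <- pair[grepl("test$", pair$scan_id) & !grepl("retest$", pair$scan_id), ]
    rts <- pair[grepl("retest$", pair$scan_id), ]
    expect_equal(tst$true_VT, rts$true_VT)
  }
  s1 <- co$sessions[[1]]; s2 <- co$sessions[[2]]
  expect_false(identical(s1$tacs[[1]]$values, s2$tacs[[1]]$values))
  expect_s3_class(s1$input_function, "input_function")
  expect_s3_class(s2$input_function, "input_function")
})

test_that("zero-noise TRT cohort has exactly zero Eq-style variability", {
  scen <- cohort_scenario(n_pos = 1, n_neg = 1, n_targets = 2,
                          noise_level = 0, seed = 2)
  co <- generate_trt_cohort(scen)
  w <- default_suv_windows()[["60-90"]]
  for (s in c("sub01", "sub02")) {
    a <- co$sessions[[paste0(s, "_test")]]
    b <- co$sessions[[paste0(s, "_retest")]]
    sv_a <- suvr_window(a$tacs[[1]], a$tacs$GMCB, w)
    sv_b <- suvr_window(b$tacs[[1]], b$tacs$GMCB, w)
    expect_equal(trt_variability(sv_a, sv_b), 0, tolerance = 1e-12)
  }
})

test_that("higher noise raises median TRT variability", {
  # 20 subjects, SUVr-based composite variability at 2% vs 10% noise
  trt_at <- function(level) {
    scen <- cohort_scenario(n_pos = 10, n_neg = 10, n_targets = 2,
                            noise_level = level, seed = 31)
    co <- generate_trt_cohort(scen)
    w <- default_suv_windows()[["60-90"]]
    vapply(sprintf("sub%02d", 1:20), function(s) {
      a <- co$sessions[[paste0(s, "_test")]]
      b <- co$sessions[[paste0(s, "_retest")]]
      trt_variability(suvr_window(a$tacs[[1]], a$tacs$GMCB, w),
                      suvr_window(b$tacs[[1]], b$tacs$GMCB, w))
    }, numeric(1))
  }
  expect_gt(median(trt_at(0.10)), median(trt_at(0.02)))
})

test_that("longitudinal cohort honours follow-up range, accumulation and drift", {
  scen <- cohort_scenario(n_pos = 3, n_neg = 2, n_targets = 2,
                          noise_level = 0, seed = 13)
  co <- generate_longitudinal_cohort(scen)
  metas <- sessions_metadata(co$sessions)
  fu <- metas$followup_years[metas$scan_role == "followup"]
  expect_true(all(fu >= 1.92 & fu <= 4.0))
  tr <- co$truth
  for (s in unique(tr$subject_id)) {
    bl <- tr[tr$scan_id == paste0(s, "_baseline"), ]
    fu_t <- tr[tr$scan_id == paste0(s, "_followup"), ]
    # white-matter drift lowers VT by the delivery factor
    yrs_s <- metas$followup_years[metas$scan_id == paste0(s, "_followup")]
    f <- (1 - 0.02)^yrs_s
    expect_equal(fu_t$true_VT[fu_t$region == "WMBS"],
                 f * bl$true_VT[bl$region == "WMBS"], tolerance = 1e-9)
    expect_equal(fu_t$true_VT[fu_t$region == "GMCB"],
                 bl$true_VT[bl$region == "GMCB"], tolerance = 1e-12)
    # positive-group mid-range subjects accumulate
    g1 <- bl$true_DVR[bl$region == bl$region[1]]
    if (g1 > 1.3 && g1 < 2.8)
      expect_gte(fu_t$true_DVR[fu_t$region == bl$region[1]], g1)
  }
  # drifted WM SUV falls while GMCB SUV is stable (noise-free)
  w <- default_suv_windows()[["60-90"]]
  rel_change <- function(s, rr) {
    a <- co$sessions[[paste0(s, "_baseline")]]
    b <- co$sessions[[paste0(s, "_followup")]]
    sa <- suv_window(a$tacs[[rr]], a$injected_dose_MBq, a$weight_kg, w)
    sb <- suv_window(b$tacs[[rr]], b$injected_dose_MBq, b$weight_kg, w)
    (sb - sa) / sa
  }
  for (s in c("sub01", "sub04")) {
    expect_lt(rel_change(s, "WMBS"), -0.02)
    expect_lt(abs(rel_change(s, "GMCB")), 0.005)
  }
})
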