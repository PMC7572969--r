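# Shared fixtures, built in code. The synthetic input and a few reference
# TACs are cached per test run because several files need them.

fx_env <- new.env(parent = emptyenv())

fx_input <- function() {
  if (is.null(fx_env$syn)) fx_env$syn <- make_synthetic_input()
  fx_env$syn
}

fx_schedule <- function() default_frame_schedule()

# Noise-free cerebellar grey matter TAC (default profile, Vb included).
fx_gmcb <- function() {
  if (is.null(fx_env$gmcb))
    fx_env$gmcb <- simulate_2t4k(kinetic_params_2t4k(0.30, 0.15, 0, 0.05, 0.03),
                                 fx_input()$input, fx_schedule(),
                                 region_label = "GMCB", volume_ml = 60)
  fx_env$gmcb
}

# Model-consistent (one-tissue, Vb = 0) reference and target: the regime in
# which reference-tissue methods are exact estimators of DVR.
fx_ref_1t <- function() {
  if (is.null(fx_env$ref1t))
    fx_env$ref1t <- simulate_2t4k(kinetic_params_2t4k(0.30, 0.15, 0, 0.05, 0),
                                  fx_input()$input, fx_schedule(),
                                  region_label = "GMCB")
  fx_env$ref1t
}

fx_target_1t <- function(dvr) {
  simulate_2t4k(kinetic_params_2t4k(0.30, 0.15 / dvr, 0, 0.05, 0),
                fx_input()$input, fx_schedule(), region_label = "target")
}

# Simple synthetic TAC from explicit frame values.
fx_tac <- function(values, sched = fx_schedule(), ...) tac(sched, values, ...)

skip_if_no_desolve <- function() skip_if_not_installed("deSolve")
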