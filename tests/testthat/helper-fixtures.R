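# Shared fixtures.  The calibrated surface is expensive (~4 s of simulated
# protocol), so it is computed lazily once per test file.

.fc_cache <- new.env(parent = emptyenv())

fc_setup <- function() {
  if (is.null(.fc_cache$setup)) {
    params <- neuron_params()
    cfg <- meander_config()
    .fc_cache$setup <- list(
      params = params, cfg = cfg,
      rev = reversal_spec(V_0_mV = params$V_rest_mV),
      surface = calibrate_firing_clamp(params, cfg))
  }
  .fc_cache$setup
}

fc_quiescent_run <- function(duration_ms = 1000) {
  key <- paste0("q", duration_ms)
  if (is.null(.fc_cache[[key]])) {
    s <- fc_setup()
    .fc_cache[[key]] <- run_firing_clamp(s$params, s$cfg, NULL, duration_ms)
  }
  .fc_cache[[key]]
}

# the published worked-example surface (bilinear polynomials in mV, pA, nS)
fig1_surface <- function() {
  calibration_surface(
    subthr = c(a_IG = 0.002, a_I = 0.079, a_G = 0.8, a_0 = -76.8),
    pulse = c(a_IG = -0.0039, a_I = 0.0477, a_G = -0.49, a_0 = -34.9),
    domain = list(I_pA = c(-50, 200), G_nS = c(0, 4)),
    form = "bilinear4", pulse_feature = "difference")
}

# simulate the neuron open-loop under dynamic-clamp control signals
fc_open_loop <- function(params, inputs, I_hold_pA = 0, V0_mV = params$V_rest_mV,
                         state0 = init_steady_state(params)) {
  sim <- firingclamp:::.fc_simulate(
    unclass(params), inputs$dt, length(inputs$I),
    firingclamp:::as_state_vector(state0), I_hold_pA, V0_mV,
    FALSE, 0, 0, 0, 0, 0, 0, inputs$I, inputs$G)
  voltage_trace(inputs$dt, sim$V, sim$I_inj)
}
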