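#' Meander (firing-clamp probe) configuration
#'
#' The probe stimulus is a biphasic "meander" repeated at `rate_Hz`: a
#' depolarizing pulse of amplitude `I_plus_pA` and fixed duration
#' `tau_plus_ms` that evokes the probe spike, immediately followed by a
#' hyperpolarizing pulse of amplitude `I_minus_pA` maintained until the
#' recorded voltage crosses `V_reset_mV` (or `tau_minus_max_ms` elapses),
#' then zero current until the next cycle start.
#'
#' Defaults follow the procedural description (600 / -400 pA, reset at
#' -75 mV); `preset = "figure1"` selects the worked-example variant
#' (400 / -300 pA, reset at -80 mV).
#'
#' @param rate_Hz probe rate (Hz)
#' @param I_plus_pA positive pulse amplitude (pA, > 0)
#' @param I_minus_pA negative pulse amplitude (pA, < 0)
#' @param tau_plus_ms positive pulse duration (ms)
#' @param V_reset_mV termination voltage for the negative pulse (mV)
#' @param tau_minus_max_ms safety cap on the negative pulse duration (ms)
#' @param spike_threshold_mV QC criterion: a cycle without a voltage
#'   excursion above this value during the positive pulse (+1 ms) is
#'   flagged as spike-failed
#' @param preset `"default"` or `"figure1"`
#' @return object of class `meander_config`
#' @export
meander_config <- function(rate_Hz = 200, I_plus_pA = 600, I_minus_pA = -400,
                           tau_plus_ms = 0.81, V_reset_mV = -75,
                           tau_minus_max_ms = 3, spike_threshold_mV = -20,
                           preset = c("default", "figure1")) {
  preset <- match.arg(preset)
  if (preset == "figure1") {
    I_plus_pA <- 400; I_minus_pA <- -300; V_reset_mV <- -80
  }
  period <- 1000 / rate_Hz
  stopifnot(rate_Hz > 0, tau_plus_ms > 0, tau_plus_ms < period,
            I_plus_pA > 0, I_minus_pA < 0,
            tau_minus_max_ms > 0, tau_minus_max_ms < period - tau_plus_ms)
  structure(list(rate_Hz = rate_Hz, I_plus_pA = I_plus_pA,
                 I_minus_pA = I_minus_pA, tau_plus_ms = tau_plus_ms,
                 V_reset_mV = V_reset_mV, tau_minus_max_ms = tau_minus_max_ms,
                 spike_threshold_mV = spike_threshold_mV),
            class = "meander_config")
}

#' @export
print.meander_config <- function(x, ...) {
  cat(sprintf("Meander: %g Hz, +%g pA for %g ms, %g pA until V <= %g mV (cap %g ms)\n",
              x$rate_Hz, x$I_plus_pA, x$tau_plus_ms, x$I_minus_pA,
              x$V_reset_mV, x$tau_minus_max_ms))
  invisible(x)
}

#' Control signals for dynamic-clamp injection
#'
#' The two signals that fully determine the subthreshold effect of
#' voltage-independent synaptic input: the total synaptic current `I`
#' measured at the resting potential, and the total synaptic conductance
#' `G`.  They are injected through the dynamic-clamp law
#' `I_inj(t) = I(t) - G(t) (V(t) - V0)`.
#'
#' @param dt_ms sampling step (ms)
#' @param I_pA injected current samples (pA, measured from rest)
#' @param G_nS injected conductance samples (nS, nonnegative)
#' @param VI_mV optional per-sample inhibitory reversal (mV), carried along
#'   for time-varying V_I scenarios
#' @return object of class `control_signals`
#' @export
control_signals <- function(dt_ms, I_pA, G_nS, VI_mV = NULL) {
  stopifnot(dt_ms > 0, length(I_pA) == length(G_nS))
  if (any(G_nS < 0)) stop("injected conductance G must be nonnegative")
  if (!is.null(VI_mV)) stopifnot(length(VI_mV) == length(I_pA))
  structure(list(dt = dt_ms, I = as.numeric(I_pA), G = as.numeric(G_nS),
                 VI = if (is.null(VI_mV)) NULL else as.numeric(VI_mV)),
            class = "control_signals")
}

#' @export
print.control_signals <- function(x, ...) {
  cat(sprintf("Control signals: %d samples, dt = %g ms, I in [%.1f, %.1f] pA, G in [%.2f, %.2f] nS%s\n",
              length(x$I), x$dt, min(x$I), max(x$I), min(x$G), max(x$G),
              if (is.null(x$VI)) "" else ", with per-sample V_I"))
  invisible(x)
}

#' Dynamic-clamp injected current
#'
#' @param I_pA simulated input current (pA, measured at `V0_mV`)
#' @param G_nS simulated input conductance (nS)
#' @param V_mV instantaneous membrane voltage (mV)
#' @param V0_mV resting potential about which the current is defined (mV)
#' @return injected current `I - G (V - V0)` in pA
#' @export
dynamic_clamp_current <- function(I_pA, G_nS, V_mV, V0_mV) {
  I_pA - G_nS * (V_mV - V0_mV)
}

#' One step of the meander state machine
#'
#' Pure-R reference implementation of the phase machine, stepped once per
#' control-loop sample with the currently recorded voltage.  The compiled
#' closed-loop simulator embeds the identical logic; this function exists
#' for controller composition with [run_neuron()] and for testing the
#' state machine in isolation against scripted voltage sequences.
#'
#' @param t_ms current time (ms)
#' @param V_mV recorded voltage at this sample (mV)
#' @param phase_state machine state as returned by the previous call, or
#'   `NULL` at the start
#' @param cfg a [meander_config()]
#' @param dt_ms control-loop step (ms)
#' @return `list(I_pA = <meander current>, phase_state = <updated state>)`
#' @export
meander_step <- function(t_ms, V_mV, phase_state, cfg, dt_ms) {
  i <- as.integer(round(t_ms / dt_ms))
  period <- 1000 / cfg$rate_Hz
  if (is.null(phase_state))
    phase_state <- list(k = -1L, s_k = 0L, s_next = 0L, p_k = 0L,
                        neg_active = FALSE)
  ps <- phase_state
  if (ps$k < 0L || i >= ps$s_next) {
    k <- ps$k + 1L
    ps$s_k <- if (ps$k < 0L) 0L else ps$s_next
    ps$s_next <- as.integer(round((k + 1) * period / dt_ms))
    ps$p_k <- ps$s_k + as.integer(round(cfg$tau_plus_ms / dt_ms))
    ps$k <- k
    ps$neg_active <- FALSE
  }
  cap_steps <- as.integer(round(cfg$tau_minus_max_ms / dt_ms))
  I <- 0
  if (i < ps$p_k) {
    I <- cfg$I_plus_pA
  } else if (i == ps$p_k) {
    ps$neg_active <- TRUE
    I <- cfg$I_minus_pA
  } else if (ps$neg_active) {
    if (V_mV <= cfg$V_reset_mV || (i - ps$p_k) >= cap_steps) {
      ps$neg_active <- FALSE
      I <- 0
    } else {
      I <- cfg$I_minus_pA
    }
  }
  list(I_pA = I, phase_state = ps)
}

resample_controls <- function(inputs, dt_ms, n_steps) {
  if (is.null(inputs)) {
    return(list(I = numeric(0), G = numeric(0)))
  }
  t_out <- (seq_len(n_steps) - 1) * dt_ms
  t_in <- (seq_along(inputs$I) - 1) * inputs$dt
  if (max(t_in) < max(t_out) - inputs$dt)
    stop("control signals do not cover the simulation duration")
  list(I = approx(t_in, inputs$I, xout = t_out, rule = 2)$y,
       G = approx(t_in, inputs$G, xout = t_out, rule = 2)$y)
}

#' Run the firing-clamp protocol in closed loop
#'
#' Simulates the model neuron under the meander probe plus dynamic-clamp
#' injection of the supplied control signals, and returns the voltage trace
#' together with per-cycle markers.  Cycles whose positive pulse fails to
#' evoke a spike (no excursion above the configured spike criterion during
#' the pulse + 1 ms) are flagged, never silently dropped.
#'
#' @param params a [neuron_params()]
#' @param cfg a [meander_config()]
#' @param inputs a [control_signals()] object covering the duration, or
#'   `NULL` for quiescent input
#' @param duration_ms simulated time (ms)
#' @param dt_ms control-loop step (ms); 0.03 ms by default
#' @param state0 initial [membrane_state()]; default resting state
#' @param I_hold_pA constant holding current (pA)
#' @param V0_mV resting potential used by the dynamic-clamp law; defaults
#'   to `params$V_rest_mV`
#' @param warmup_ms length of a discarded quiescent firing-clamp run used
#'   to settle the slow gates onto the periodic probe-spiking attractor
#'   before recording starts (ms)
#' @return `list(trace = voltage_trace, markers = data.frame)` where the
#'   markers hold, per cycle: 1-based sample indices of the cycle start,
#'   positive-pulse end, negative-pulse end and cycle end, the matching
#'   times (ms), how the negative pulse terminated (`"voltage_cross"` or
#'   `"cap"`), and `spike` (logical QC flag)
#' @export
run_firing_clamp <- function(params, cfg, inputs = NULL, duration_ms,
                             dt_ms = 0.03, state0 = NULL, I_hold_pA = 0,
                             V0_mV = NULL, warmup_ms = 200) {
  stopifnot(inherits(params, "neuron_params"), inherits(cfg, "meander_config"),
            dt_ms > 0, dt_ms <= 0.05)
  if (is.null(state0)) state0 <- init_steady_state(params)
  if (is.null(V0_mV)) V0_mV <- params$V_rest_mV
  if (warmup_ms > 0) {
    # whole probe cycles only, so the run starts at a cycle boundary of
    # the settled attractor
    warmup_ms <- round(warmup_ms * cfg$rate_Hz / 1000) * 1000 / cfg$rate_Hz
    wu <- .fc_simulate(unclass(params), dt_ms,
                       as.integer(round(warmup_ms / dt_ms)),
                       as_state_vector(state0), I_hold_pA, V0_mV,
                       TRUE, cfg$rate_Hz, cfg$I_plus_pA, cfg$I_minus_pA,
                       cfg$tau_plus_ms, cfg$V_reset_mV, cfg$tau_minus_max_ms,
                       numeric(0), numeric(0))
    state0 <- state_from_vector(wu$state)
  }
  n <- as.integer(round(duration_ms / dt_ms))
  rc <- resample_controls(inputs, dt_ms, n)
  sim <- .fc_simulate(unclass(params), dt_ms, n, as_state_vector(state0),
                      I_hold_pA, V0_mV,
                      TRUE, cfg$rate_Hz, cfg$I_plus_pA, cfg$I_minus_pA,
                      cfg$tau_plus_ms, cfg$V_reset_mV, cfg$tau_minus_max_ms,
                      rc$I, rc$G)
  trace <- voltage_trace(dt_ms, sim$V, sim$I_inj)
  mk <- data.frame(cycle = seq_along(sim$cycle_start),
                   i_start = sim$cycle_start, i_pulse_end = sim$pulse_end,
                   i_neg_end = sim$neg_end, i_cycle_end = sim$cycle_end)
  mk$t_start <- (mk$i_start - 1) * dt_ms
  mk$t_pulse_end <- (mk$i_pulse_end - 1) * dt_ms
  mk$t_neg_end <- (mk$i_neg_end - 1) * dt_ms
  mk$t_cycle_end <- mk$i_cycle_end * dt_ms
  mk$terminated_by <- c("positive", "voltage_cross", "cap")[sim$terminated_by + 1L]
  # QC: probe spike present during the positive pulse + 1 ms
  qc_extra <- as.integer(round(1 / dt_ms))
  mk$spike <- vapply(seq_len(nrow(mk)), function(j) {
    hi <- min(mk$i_pulse_end[j] + qc_extra, length(trace$V))
    max(trace$V[mk$i_start[j]:hi]) > cfg$spike_threshold_mV
  }, logical(1))
  class(mk) <- c("cycle_markers", "data.frame")
  list(trace = trace, markers = mk)
}
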