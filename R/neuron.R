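#' Neuron model parameters
#'
#' Parameters of the single-compartment conductance-based model used for
#' protocol simulation: a leak, a transient sodium current (m^3 h), a
#' delayed-rectifier potassium current (n^4) and a slow potassium
#' adaptation current gated by `w` (tau ~ 100 ms).  Defaults describe a
#' small dissociated cell: 12 pF, 1.5 nS input conductance, resting near
#' -77 mV, firing a single probe spike per 0.81 ms / 600 pA pulse.
#'
#' @param C_pF membrane capacitance (pF)
#' @param G_leak_nS resting (leak) input conductance G_0 (nS)
#' @param V_rest_mV leak reversal / resting potential V_0 (mV)
#' @param gbar_Na_nS,gbar_K_nS,gbar_AHP_nS maximal channel conductances (nS)
#' @param E_Na_mV,E_K_mV channel reversal potentials (mV)
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(C_pF = 12, G_leak_nS = 1.5, V_rest_mV = -77,
                          gbar_Na_nS = 350, gbar_K_nS = 100,
                          gbar_AHP_nS = 5, E_Na_mV = 55, E_K_mV = -90) {
  stopifnot(C_pF > 0, G_leak_nS > 0,
            gbar_Na_nS >= 0, gbar_K_nS >= 0, gbar_AHP_nS >= 0)
  if (!(E_Na_mV > V_rest_mV && V_rest_mV > E_K_mV))
    stop("reversal potentials must satisfy E_Na > V_rest > E_K")
  structure(list(C_pF = C_pF, G_leak_nS = G_leak_nS, V_rest_mV = V_rest_mV,
                 gbar_Na_nS = gbar_Na_nS, gbar_K_nS = gbar_K_nS,
                 gbar_AHP_nS = gbar_AHP_nS, E_Na_mV = E_Na_mV,
                 E_K_mV = E_K_mV),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Single-compartment neuron model\n")
  cat(sprintf("  C = %g pF, G_leak = %g nS, V_rest = %g mV\n",
              x$C_pF, x$G_leak_nS, x$V_rest_mV))
  cat(sprintf("  gbar: Na %g, K %g, AHP %g nS;  E_Na %g, E_K %g mV\n",
              x$gbar_Na_nS, x$gbar_K_nS, x$gbar_AHP_nS, x$E_Na_mV, x$E_K_mV))
  invisible(x)
}

#' Membrane state
#'
#' @param V membrane voltage (mV)
#' @param m,h,n,w gating variables in `[0, 1]`
#' @return object of class `membrane_state`
#' @export
membrane_state <- function(V, m, h, n, w) {
  g <- c(m = m, h = h, n = n, w = w)
  if (any(g < 0 | g > 1)) stop("gating variables must lie in [0, 1]")
  if (!is.finite(V)) stop("membrane voltage must be finite")
  structure(list(V = V, m = m, h = h, n = n, w = w), class = "membrane_state")
}

as_state_vector <- function(state) {
  c(state$V, state$m, state$h, state$n, state$w)
}

state_from_vector <- function(v) {
  membrane_state(v[1], v[2], v[3], v[4], v[5])
}

#' Resting state of the model
#'
#' Relaxes the model with zero injected current until it settles at its
#' resting fixed point, then verifies the fixed point by a single step.
#'
#' @param params a [neuron_params()] object
#' @param relax_ms relaxation horizon (ms)
#' @param dt_ms integration step (ms)
#' @param tol maximum tolerated |dV/dt| at the fixed point (mV/ms)
#' @return a [membrane_state()] at rest
#' @export
init_steady_state <- function(params, relax_ms = 2000, dt_ms = 0.025,
                              tol = 1e-6) {
  gi <- .fc_gate_inf(params$V_rest_mV)
  s0 <- c(params$V_rest_mV, gi)
  sim <- .fc_simulate(unclass(params), dt_ms, as.integer(round(relax_ms / dt_ms)),
                      s0, 0, params$V_rest_mV,
                      FALSE, 0, 0, 0, 0, 0, 0, numeric(0), numeric(0))
  s <- sim$state
  s1 <- .fc_model_step(unclass(params), s, 0, dt_ms)
  if (abs(s1[1] - s[1]) / dt_ms > tol)
    stop("no stable resting state found: |dV/dt| = ",
         format(abs(s1[1] - s[1]) / dt_ms), " mV/ms after relaxation")
  state_from_vector(s)
}

#' Advance the membrane state one step
#'
#' Exponential (exact-relaxation) update of the gates at frozen voltage
#' followed by exponential update of the voltage at frozen gates.
#'
#' @param state a [membrane_state()]
#' @param I_inj_pA injected current held constant over the step (pA)
#' @param dt_ms step (ms), at most 0.05
#' @param params a [neuron_params()]
#' @return the advanced [membrane_state()]
#' @export
step_neuron <- function(state, I_inj_pA, dt_ms, params) {
  stopifnot(dt_ms > 0, dt_ms <= 0.05)
  state_from_vector(.fc_model_step(unclass(params), as_state_vector(state),
                                   I_inj_pA, dt_ms))
}

#' Uniformly sampled voltage / injected-current trace
#'
#' @param dt_ms sampling step (ms)
#' @param V_mV voltage samples (mV)
#' @param Iinj_pA injected-current samples (pA), same length as `V_mV`
#' @param t0_ms start time (ms)
#' @return object of class `voltage_trace`
#' @export
voltage_trace <- function(dt_ms, V_mV, Iinj_pA = rep(0, length(V_mV)),
                          t0_ms = 0) {
  stopifnot(dt_ms > 0, length(V_mV) == length(Iinj_pA))
  structure(list(dt = dt_ms, t0 = t0_ms, V = as.numeric(V_mV),
                 I_inj = as.numeric(Iinj_pA)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples, dt = %g ms (%.4g ms), V in [%.2f, %.2f] mV\n",
              length(x$V), x$dt, length(x$V) * x$dt, min(x$V), max(x$V)))
  invisible(x)
}

#' Trace time stamps
#' @param trace a [voltage_trace()]
#' @return numeric vector of sample times (ms)
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$V) - 1) * trace$dt
}

#' Run the model under an arbitrary causal current controller
#'
#' The controller is called once per step with the current time and the
#' voltage at the start of the step (sample-and-hold: it never sees future
#' samples), mirroring a discrete dynamic-clamp control loop.
#'
#' @param params a [neuron_params()]
#' @param controller `function(t_ms, V_mV) -> I_inj_pA`
#' @param duration_ms simulated time (ms)
#' @param dt_ms control-loop step (ms)
#' @param state0 initial [membrane_state()]; default is the resting state
#' @return a [voltage_trace()]
#' @export
run_neuron <- function(params, controller, duration_ms, dt_ms = 0.03,
                       state0 = NULL) {
  stopifnot(dt_ms > 0, dt_ms <= 0.05)
  if (is.null(state0)) state0 <- init_steady_state(params)
  n <- as.integer(round(duration_ms / dt_ms))
  s <- as_state_vector(state0)
  V <- numeric(n); I <- numeric(n)
  p <- unclass(params)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt_ms
    V[i] <- s[1]
    I[i] <- controller(t, s[1])
    s <- .fc_model_step(p, s, I[i], dt_ms)
  }
  voltage_trace(dt_ms, V, I)
}
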