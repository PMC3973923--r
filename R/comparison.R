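#' Multi-trial continuous current-clamp conductance estimation
#'
#' The reference method: record the membrane voltage repeatedly under the
#' same input scenario at two or more distinct holding currents, and at
#' every time point solve the passive membrane equation
#' `C dV_k/dt = I_hold,k + I(t) - (G_leak + G(t)) (V_k(t) - V_rest)`
#' for the two unknowns I(t) and G(t) (least squares across trials,
#' central-difference derivative), then decompose into (G_E, G_I).
#' Time points where the traces nearly coincide (singular system) or where
#' any trace is suprathreshold are flagged and interpolated before the
#' optional zero-phase low-pass filter.
#'
#' @param traces list of [voltage_trace()] objects of equal length and dt
#' @param I_hold_pA holding current of each trace (pA), all distinct
#' @param params a [neuron_params()] supplying the passive parameters
#'   (C_m, G_leak, V_rest)
#' @param rev a [reversal_spec()]
#' @param filter_cutoff_Hz zero-phase 2nd-order Butterworth low-pass
#'   cutoff applied to the estimated I and G series; `NULL` disables
#' @param spike_threshold_mV points where any trace exceeds this voltage
#'   are flagged as spike-contaminated
#' @param min_spread_mV minimum across-trial voltage spread for a point to
#'   be considered well-conditioned (mV)
#' @return data frame `t_ms`, `I_pA`, `G_nS`, `GE_nS`, `GI_nS`, `ok`
#' @export
estimate_continuous <- function(traces, I_hold_pA, params, rev,
                                filter_cutoff_Hz = 50,
                                spike_threshold_mV = -50,
                                min_spread_mV = 0.5) {
  K <- length(traces)
  stopifnot(K >= 2, length(I_hold_pA) == K,
            !anyDuplicated(I_hold_pA), inherits(params, "neuron_params"))
  n <- length(traces[[1]]$V)
  dt <- traces[[1]]$dt
  for (tr in traces) stopifnot(length(tr$V) == n, tr$dt == dt)
  V <- do.call(cbind, lapply(traces, `[[`, "V"))
  dVdt <- apply(V, 2, function(v) {
    c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  })
  C <- params$C_pF; gL <- params$G_leak_nS; V0 <- params$V_rest_mV
  # row-wise 2-unknown least squares: [1, -(V_k - V0)] (I, G)' = y_k
  # with y_k = C dV_k/dt - I_hold_k + gL (V_k - V0)
  Y <- sweep(C * dVdt + gL * (V - V0), 2, I_hold_pA, "-")
  D <- V - V0
  Sx <- rowSums(D); Sxx <- rowSums(D^2)
  Sy <- rowSums(Y); Sxy <- rowSums(D * Y)
  det <- K * Sxx - Sx^2
  G <- -(K * Sxy - Sx * Sy) / det
  I <- (Sy + G * Sx) / K
  spread <- apply(D, 1, function(r) diff(range(r)))
  ok <- is.finite(I) & is.finite(G) & spread >= min_spread_mV &
    apply(V, 1, max) <= spike_threshold_mV
  fill <- function(x) {
    if (all(ok)) return(x)
    idx <- which(ok)
    if (length(idx) < 2) stop("too few well-conditioned time points")
    approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
  }
  I <- fill(I); G <- fill(G)
  if (!is.null(filter_cutoff_Hz)) {
    fs <- 1000 / dt
    bf <- signal::butter(2, filter_cutoff_Hz / (fs / 2), type = "low")
    I <- signal::filtfilt(bf, I)
    G <- signal::filtfilt(bf, G)
  }
  dec <- decompose_conductances(I, G, rev)
  data.frame(t_ms = trace_times(traces[[1]]), I_pA = I, G_nS = G,
             GE_nS = dec$G_E_nS, GI_nS = dec$G_I_nS, ok = ok)
}

#' Hyperpolarizing pulse-probe conductance estimation
#'
#' The naive single-trial method: a train of small hyperpolarizing current
#' pulses under current clamp, with the total input conductance read from
#' each steady-state voltage deflection through Ohm's law,
#' `G = I_pulse / deltaV`.  Its sampling rate is limited by the membrane
#' time constant, since each deflection must settle; the comparison with
#' the firing clamp's per-cycle sampling is the point of this estimator.
#'
#' @param trace a [voltage_trace()] recorded under the pulse train
#' @param pulse_pA pulse amplitude (pA, negative)
#' @param period_ms pulse repetition period (ms)
#' @param pulse_ms pulse duration (ms); should be several membrane time
#'   constants for the deflection to settle
#' @param t0_ms time of the first pulse onset (ms)
#' @param baseline_ms averaging window just before each pulse onset and at
#'   the pulse end (ms)
#' @param min_deflection_mV flag samples whose deflection is below this
#'   floor
#' @return data frame `t_ms`, `G_nS`, `ok`
#' @export
estimate_pulse_probe <- function(trace, pulse_pA, period_ms, pulse_ms,
                                 t0_ms = 0, baseline_ms = 2,
                                 min_deflection_mV = 0.5) {
  stopifnot(pulse_pA < 0, pulse_ms < period_ms)
  dt <- trace$dt
  n <- length(trace$V)
  bl <- max(1L, as.integer(round(baseline_ms / dt)))
  onsets <- seq(t0_ms, (n - 1) * dt - pulse_ms, by = period_ms)
  res <- lapply(onsets, function(on) {
    i_on <- as.integer(round(on / dt)) + 1L
    i_end <- as.integer(round((on + pulse_ms) / dt))
    if (i_on - bl < 1 || i_end > n) return(NULL)
    v_base <- mean(trace$V[(i_on - bl):(i_on - 1)])
    v_end <- mean(trace$V[(i_end - bl + 1):i_end])
    dV <- v_end - v_base
    ok <- abs(dV) >= min_deflection_mV
    data.frame(t_ms = on + pulse_ms, G_nS = if (ok) pulse_pA / dV else NA_real_,
               ok = ok)
  })
  do.call(rbind, res)
}

#' Current source for a hyperpolarizing pulse train
#'
#' Convenience controller for [run_neuron()] implementing the pulse-probe
#' stimulus.
#'
#' @inheritParams estimate_pulse_probe
#' @return `function(t_ms, V_mV) -> pA`
#' @export
pulse_train_controller <- function(pulse_pA, period_ms, pulse_ms,
                                   t0_ms = 0) {
  function(t, V) {
    ph <- (t - t0_ms) %% period_ms
    if (t >= t0_ms && ph < pulse_ms) pulse_pA else 0
  }
}

#' Sampling-bandwidth ratio of firing clamp vs noise-based estimation
#'
#' Noise-statistics conductance estimators need statistically stationary
#' stretches of roughly `stationarity_ms` (about 100 ms), whereas the
#' firing clamp delivers one independent estimate per probe cycle
#' (5 ms at 200 Hz), giving a bandwidth advantage of a factor of 20 or
#' more.
#'
#' @param stationarity_ms stationarity window of the noise-based method
#'   (ms)
#' @param probe_rate_Hz firing-clamp probe rate (Hz)
#' @return the dimensionless ratio `stationarity_ms / probe period`
#' @export
bandwidth_ratio <- function(stationarity_ms = 100, probe_rate_Hz = 200) {
  stationarity_ms / (1000 / probe_rate_Hz)
}
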