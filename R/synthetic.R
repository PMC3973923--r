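#' Synthetic synaptic-input scenario
#'
#' Ground-truth generators mirroring the validation scenarios: sinusoidal
#' conductance oscillations in the gamma (40 Hz default) or theta (6 Hz
#' default) range, Poisson trains of instantaneous-rise /
#' mono-exponential-decay synaptic events, smoothed agonist application
#' steps, linear chirps for bandwidth probing, additive Gaussian noise
#' (clipped at zero conductance), and an optional linear drift of the
#' inhibitory reversal potential.
#'
#' Each of the excitatory and inhibitory channels is a list of components;
#' a component is created with [sc_sinusoid()], [sc_events()],
#' [sc_step()] or [sc_chirp()].
#'
#' @param E,I component or list of components for G_E and G_I (nS)
#' @param noise_sd_nS additive Gaussian noise s.d. applied to both
#'   conductance traces (nS)
#' @param vi_drift optional `list(from_mV, to_mV, onset_ms, offset_ms)`
#'   describing a linear drift of V_I (held constant outside the ramp)
#' @param seed RNG seed; a fixed seed makes the generator fully
#'   deterministic
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(E = list(), I = list(), noise_sd_nS = 0,
                          vi_drift = NULL, seed = 1L) {
  as_components <- function(x) {
    if (inherits(x, "sc_component")) list(x)
    else if (is.list(x) && (length(x) == 0 ||
             all(vapply(x, inherits, TRUE, "sc_component")))) x
    else stop("scenario components must be built with sc_sinusoid(), ",
              "sc_events(), sc_step() or sc_chirp()")
  }
  stopifnot(noise_sd_nS >= 0)
  structure(list(E = as_components(E), I = as_components(I),
                 noise_sd_nS = noise_sd_nS, vi_drift = vi_drift,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Scenario components
#'
#' @param freq_Hz oscillation frequency (Hz)
#' @param amp_nS oscillation amplitude or event/step amplitude (nS)
#' @param mean_nS sinusoid baseline (nS); defaults to the amplitude so the
#'   oscillation touches zero
#' @param phase_rad starting phase (rad)
#' @param onset_ms,offset_ms active interval (ms); `Inf` = until the end
#' @return object of class `sc_component`
#' @rdname scenario-components
#' @export
sc_sinusoid <- function(freq_Hz, amp_nS, mean_nS = amp_nS, phase_rad = 0,
                        onset_ms = 0, offset_ms = Inf) {
  stopifnot(freq_Hz > 0, amp_nS >= 0, mean_nS >= 0)
  structure(list(kind = "sinusoid", freq_Hz = freq_Hz, amp_nS = amp_nS,
                 mean_nS = mean_nS, phase_rad = phase_rad,
                 onset_ms = onset_ms, offset_ms = offset_ms),
            class = "sc_component")
}

#' @param rate_Hz mean Poisson event rate (Hz)
#' @param tau_ms mono-exponential decay time constant (ms)
#' @rdname scenario-components
#' @export
sc_events <- function(rate_Hz, amp_nS, tau_ms, onset_ms = 0,
                      offset_ms = Inf) {
  stopifnot(rate_Hz >= 0, amp_nS >= 0, tau_ms > 0)
  structure(list(kind = "event_train", rate_Hz = rate_Hz, amp_nS = amp_nS,
                 tau_ms = tau_ms, onset_ms = onset_ms, offset_ms = offset_ms),
            class = "sc_component")
}

#' @param ramp_ms rise/fall time of the agonist application edges (ms)
#' @rdname scenario-components
#' @export
sc_step <- function(amp_nS, onset_ms, offset_ms, ramp_ms = 200) {
  stopifnot(amp_nS >= 0, ramp_ms >= 0, offset_ms > onset_ms)
  structure(list(kind = "agonist_step", amp_nS = amp_nS, onset_ms = onset_ms,
                 offset_ms = offset_ms, ramp_ms = ramp_ms),
            class = "sc_component")
}

#' @param f0_Hz,f1_Hz chirp start and end frequency (Hz), swept linearly
#'   over the active interval
#' @rdname scenario-components
#' @export
sc_chirp <- function(f0_Hz, f1_Hz, amp_nS, mean_nS = amp_nS, onset_ms = 0,
                     offset_ms = Inf) {
  stopifnot(f0_Hz >= 0, f1_Hz >= 0, amp_nS >= 0, mean_nS >= 0)
  structure(list(kind = "chirp", f0_Hz = f0_Hz, f1_Hz = f1_Hz,
                 amp_nS = amp_nS, mean_nS = mean_nS, onset_ms = onset_ms,
                 offset_ms = offset_ms),
            class = "sc_component")
}

component_trace <- function(comp, t) {
  on <- t >= comp$onset_ms & t < comp$offset_ms
  g <- numeric(length(t))
  tt <- t[on] - comp$onset_ms
  if (comp$kind == "sinusoid") {
    g[on] <- comp$mean_nS +
      comp$amp_nS * sin(2 * pi * comp$freq_Hz * tt / 1000 + comp$phase_rad)
  } else if (comp$kind == "chirp") {
    T <- if (is.finite(comp$offset_ms)) comp$offset_ms - comp$onset_ms
         else max(tt)
    phase <- 2 * pi * (comp$f0_Hz * tt / 1000 +
                         (comp$f1_Hz - comp$f0_Hz) * tt^2 / (2 * T) / 1000)
    g[on] <- comp$mean_nS + comp$amp_nS * sin(phase)
  } else if (comp$kind == "agonist_step") {
    r <- max(comp$ramp_ms, .Machine$double.eps)
    up <- pmin(pmax((t - comp$onset_ms) / r, 0), 1)
    down <- pmin(pmax((comp$offset_ms - t) / r, 0), 1)
    g <- comp$amp_nS * pmin(up, down)
  } else if (comp$kind == "event_train") {
    T_ms <- (if (is.finite(comp$offset_ms)) comp$offset_ms else max(t)) -
      comp$onset_ms
    n_ev <- stats::rpois(1, comp$rate_Hz * T_ms / 1000)
    if (n_ev > 0) {
      t_ev <- sort(stats::runif(n_ev, comp$onset_ms, comp$onset_ms + T_ms))
      for (te in t_ev) {
        idx <- t >= te
        g[idx] <- g[idx] + comp$amp_nS * exp(-(t[idx] - te) / comp$tau_ms)
      }
    }
    attr(g, "event_times_ms") <- if (n_ev > 0) t_ev else numeric(0)
  }
  g
}

#' Generate ground-truth conductance traces for a scenario
#'
#' Runs the scenario's random components under its own seed (the global
#' RNG state is saved and restored), sums components per channel, adds
#' clipped Gaussian noise, and evaluates the V_I drift when requested.
#'
#' @param spec a [scenario_spec()]
#' @param duration_ms trace length (ms)
#' @param dt_ms sampling step (ms)
#' @return `list(dt_ms, t_ms, G_E_nS, G_I_nS, VI_mV)` with `VI_mV = NULL`
#'   unless the scenario drifts V_I
#' @export
generate_scenario <- function(spec, duration_ms, dt_ms = 0.03) {
  stopifnot(inherits(spec, "scenario_spec"))
  t <- (seq_len(as.integer(round(duration_ms / dt_ms))) - 1) * dt_ms
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  sum_channel <- function(comps) {
    g <- numeric(length(t))
    for (comp in comps) g <- g + component_trace(comp, t)
    g
  }
  GE <- sum_channel(spec$E)
  GI <- sum_channel(spec$I)
  if (spec$noise_sd_nS > 0) {
    GE <- GE + rnorm(length(t), 0, spec$noise_sd_nS)
    GI <- GI + rnorm(length(t), 0, spec$noise_sd_nS)
  }
  GE <- pmax(GE, 0); GI <- pmax(GI, 0)
  VI <- NULL
  if (!is.null(spec$vi_drift)) {
    d <- spec$vi_drift
    frac <- pmin(pmax((t - d$onset_ms) / (d$offset_ms - d$onset_ms), 0), 1)
    VI <- d$from_mV + (d$to_mV - d$from_mV) * frac
  }
  list(dt_ms = dt_ms, t_ms = t, G_E_nS = GE, G_I_nS = GI, VI_mV = VI)
}

#' Convert ground-truth conductances to dynamic-clamp control signals
#'
#' Applies the forward control-signal equations pointwise
#' (see [compose_conductances()]) so a scenario can be injected through
#' the dynamic-clamp law.
#'
#' @param gen output of [generate_scenario()]
#' @param rev a [reversal_spec()]
#' @return a [control_signals()] object (carrying the per-sample V_I when
#'   the scenario drifts it)
#' @export
to_control_signals <- function(gen, rev) {
  VI <- if (is.null(gen$VI_mV)) rev$V_I else gen$VI_mV
  cs <- compose_conductances(gen$G_E_nS, gen$G_I_nS,
                             reversal_spec(rev$V_E, VI, rev$V_0))
  control_signals(gen$dt_ms, cs$I_pA, cs$G_nS,
                  VI_mV = if (is.null(gen$VI_mV)) NULL else gen$VI_mV)
}

#' Cycle-averaged ground truth
#'
#' Averages a per-sample ground-truth trace over each probe-cycle window,
#' i.e. the best-resolved signal the per-cycle estimator could possibly
#' report (one value per cycle).
#'
#' @param x per-sample numeric vector aligned with the simulation trace
#' @param markers cycle markers from [run_firing_clamp()]
#' @return numeric vector, one mean per cycle
#' @export
cycle_average <- function(x, markers) {
  vapply(seq_len(nrow(markers)), function(j) {
    mean(x[markers$i_start[j]:markers$i_cycle_end[j]])
  }, 0)
}
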