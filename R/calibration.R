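#' Sinusoidal calibration control signals
#'
#' During calibration, slow sinusoidal current and conductance are injected
#' on top of the meander so that the per-cycle mean (I, G) points sweep the
#' physiologically meaningful domain of the I-G plane.  The two periods
#' (40 and 70 ms by default) are chosen incommensurate with each other and
#' with the probe period so the Lissajous trajectory fills the rectangle.
#'
#' @param periods_ms lengths of the I and G sinusoid periods (ms)
#' @param I_range_pA `c(min, max)` for the current sinusoid (pA)
#' @param G_range_nS `c(min, max)` for the conductance sinusoid (nS);
#'   generated G is clipped at zero
#' @param duration_ms total length (ms)
#' @param dt_ms sampling step (ms)
#' @param probe_period_ms probe cycle length used for the commensurability
#'   check (ms); `NULL` to skip
#' @return a [control_signals()] object
#' @export
make_calibration_signals <- function(periods_ms = c(40, 70),
                                     I_range_pA = c(0, 50),
                                     G_range_nS = c(0, 4),
                                     duration_ms = 2000, dt_ms = 0.03,
                                     probe_period_ms = 5) {
  stopifnot(length(periods_ms) == 2, all(periods_ms > 0))
  if (diff(I_range_pA) < 0 || diff(G_range_nS) < 0)
    stop("degenerate range: max must be >= min")
  # An integer ratio between the two sinusoid periods closes the Lissajous
  # trajectory onto a line-like figure and the cycle-mean (I, G) points
  # cannot fill the rectangle.  (A period that is an integer multiple of
  # the probe period is harmless: the per-cycle means then sample a fixed
  # lattice of phases, which still covers the domain.)
  near_int <- function(x) abs(x - round(x)) < 1e-9 & round(x) != 0
  r <- periods_ms[1] / periods_ms[2]
  if (near_int(r) || near_int(1 / r) ||
      (!is.null(probe_period_ms) && any(abs(periods_ms - probe_period_ms) <
                                          1e-9)))
    warning("calibration periods are commensurate; (I, G) coverage of the ",
            "domain may be poor")
  t <- (seq_len(as.integer(round(duration_ms / dt_ms))) - 1) * dt_ms
  mid <- function(r) mean(r)
  amp <- function(r) diff(r) / 2
  I <- mid(I_range_pA) + amp(I_range_pA) * sin(2 * pi * t / periods_ms[1])
  G <- mid(G_range_nS) + amp(G_range_nS) * sin(2 * pi * t / periods_ms[2])
  control_signals(dt_ms, I, pmax(G, 0))
}

#' Per-cycle averages of the control signals
#'
#' Associates the slowly varying injected signals with each probe cycle by
#' averaging them over the cycle window.
#'
#' @param inputs a [control_signals()] object
#' @param markers cycle markers from [run_firing_clamp()]
#' @return data frame `cycle`, `I_pA`, `G_nS` (and `VI_mV` when the inputs
#'   carry a per-sample inhibitory reversal)
#' @export
cycle_average_controls <- function(inputs, markers) {
  win_mean <- function(x, j) {
    mean(x[markers$i_start[j]:markers$i_cycle_end[j]])
  }
  idx <- seq_len(nrow(markers))
  out <- data.frame(cycle = markers$cycle,
                    I_pA = vapply(idx, function(j) win_mean(inputs$I, j), 0),
                    G_nS = vapply(idx, function(j) win_mean(inputs$G, j), 0))
  if (!is.null(inputs$VI))
    out$VI_mV <- vapply(idx, function(j) win_mean(inputs$VI, j), 0)
  out
}

#' Construct a calibration surface from coefficients
#'
#' Each feature surface is a polynomial in the injected (I, G):
#' the `bilinear4` form `a_IG*I*G + a_I*I + a_G*G + a_0` (the terms present
#' in the worked-example polynomials) or the full `quadratic6` form with
#' additional `a_II*I^2 + a_GG*G^2`.
#'
#' @param subthr,pulse named coefficient vectors (`a_IG`, `a_I`, `a_G`,
#'   `a_0`, and for `quadratic6` also `a_II`, `a_GG`); units mV/(pA nS),
#'   mV/pA, mV/nS, mV
#' @param domain list with `I_pA = c(min, max)`, `G_nS = c(min, max)`
#' @param form `"bilinear4"` or `"quadratic6"`
#' @param residual_rms_mV per-feature residual RMS of the fit (mV)
#' @param n_points number of calibration points used
#' @param pulse_feature feature convention the surface was fitted with
#' @return object of class `calibration_surface`
#' @export
calibration_surface <- function(subthr, pulse, domain,
                                form = c("bilinear4", "quadratic6"),
                                residual_rms_mV = c(subthr = NA_real_,
                                                    pulse = NA_real_),
                                n_points = NA_integer_,
                                pulse_feature = "peak") {
  form <- match.arg(form)
  need <- c("a_IG", "a_I", "a_G", "a_0")
  if (form == "quadratic6") need <- c(need, "a_II", "a_GG")
  for (co in list(subthr, pulse)) {
    miss <- setdiff(need, names(co))
    if (length(miss)) stop("missing coefficients: ", paste(miss, collapse = ", "))
  }
  if (diff(domain$I_pA) <= 0 || diff(domain$G_nS) <= 0)
    stop("degenerate fit domain")
  structure(list(subthr = subthr[need], pulse = pulse[need], domain = domain,
                 form = form, residual_rms_mV = residual_rms_mV,
                 n_points = n_points, pulse_feature = pulse_feature),
            class = "calibration_surface")
}

#' @export
print.calibration_surface <- function(x, ...) {
  fmt <- function(co) paste(sprintf("%s=%.6g", names(co), co), collapse = ", ")
  cat(sprintf("Calibration surface (%s, V_pulse as %s)\n", x$form,
              x$pulse_feature))
  cat("  V_subthr: ", fmt(x$subthr), "\n", sep = "")
  cat("  V_pulse:  ", fmt(x$pulse), "\n", sep = "")
  cat(sprintf("  domain: I in [%g, %g] pA, G in [%g, %g] nS; n = %s; RMS = %.3g / %.3g mV\n",
              x$domain$I_pA[1], x$domain$I_pA[2], x$domain$G_nS[1],
              x$domain$G_nS[2], format(x$n_points),
              x$residual_rms_mV[1], x$residual_rms_mV[2]))
  invisible(x)
}

surface_design <- function(I, G, form) {
  X <- cbind(a_IG = I * G, a_I = I, a_G = G, a_0 = 1)
  if (form == "quadratic6") X <- cbind(X, a_II = I^2, a_GG = G^2)
  X
}

#' Fit the two calibration surfaces by least squares
#'
#' Ordinary least squares of each measured feature against the per-cycle
#' injected (I, G), using the bilinear 4-term basis by default or the full
#' quadratic 6-term basis.
#'
#' @param features a [probe_features()] series
#' @param controls per-cycle controls from [cycle_average_controls()]
#' @param form `"bilinear4"` or `"quadratic6"`
#' @return a [calibration_surface()]
#' @export
fit_surfaces <- function(features, controls,
                         form = c("bilinear4", "quadratic6")) {
  form <- match.arg(form)
  df <- merge(as.data.frame(features), controls, by = "cycle")
  df <- df[df$qc == "ok" & is.finite(df$Vsubthr_mV) & is.finite(df$Vpulse_mV), ]
  p <- if (form == "bilinear4") 4L else 6L
  if (nrow(df) < p)
    stop("need at least ", p, " unflagged calibration points, got ", nrow(df))
  X <- surface_design(df$I_pA, df$G_nS, form)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("rank-deficient calibration design (rank ", qrX$rank, " < ", p,
         "): calibration points do not span the I-G plane (collinear or ",
         "constant I, G)")
  fit1 <- qr.coef(qrX, df$Vsubthr_mV)
  fit2 <- qr.coef(qrX, df$Vpulse_mV)
  rms <- function(co, y) sqrt(mean((y - drop(X %*% co))^2))
  pf <- attr(features, "pulse_feature")
  calibration_surface(
    subthr = stats::setNames(fit1, colnames(X)),
    pulse = stats::setNames(fit2, colnames(X)),
    domain = list(I_pA = range(df$I_pA), G_nS = range(df$G_nS)),
    form = form,
    residual_rms_mV = c(subthr = rms(fit1, df$Vsubthr_mV),
                        pulse = rms(fit2, df$Vpulse_mV)),
    n_points = nrow(df),
    pulse_feature = if (is.null(pf)) "peak" else pf)
}

#' Evaluate a calibration surface
#'
#' @param surface a [calibration_surface()]
#' @param I_pA,G_nS injected current and conductance (vectorized)
#' @param warn_extrapolation warn when a point lies outside the fit domain
#' @return `list(V_subthr_mV, V_pulse_mV)`
#' @export
evaluate_surface <- function(surface, I_pA, G_nS, warn_extrapolation = TRUE) {
  stopifnot(inherits(surface, "calibration_surface"))
  X <- surface_design(I_pA, G_nS, surface$form)
  if (warn_extrapolation) {
    out <- I_pA < surface$domain$I_pA[1] | I_pA > surface$domain$I_pA[2] |
      G_nS < surface$domain$G_nS[1] | G_nS > surface$domain$G_nS[2]
    if (any(out))
      warning(sum(out), " point(s) outside the calibration domain; ",
              "surface extrapolated")
  }
  list(V_subthr_mV = drop(X %*% surface$subthr),
       V_pulse_mV = drop(X %*% surface$pulse))
}

#' Calibrate the firing clamp on a simulated neuron
#'
#' Ties the calibration loop together: inject calibration stimuli on top
#' of the meander, run the firing-clamp protocol, extract the per-cycle
#' features, pair them with the injected (I, G), and fit the two response
#' surfaces.
#'
#' Two stimulus designs are available.  The default `"grid"` steps
#' through an I x G lattice of constant injections (one short segment per
#' point, the first `settle_cycles` probe cycles of each segment
#' discarded); because every feature pair is measured in a settled state,
#' the fitted surface is free of the history effects that slowly varying
#' stimuli leave in the per-cycle features.  The quiescent lattice point
#' (I = 0, G = 0) is recorded `quiescent_oversample` times longer than
#' the others: every later recording's baseline sits at that point, so
#' anchoring the fit there costs nothing and stabilises estimates around
#' rest.  `"sinusoid"` reproduces the classic procedure -- slow
#' incommensurate sine waves in I and G (see
#' [make_calibration_signals()]) with per-cycle averages of the injected
#' signals as regressors.
#'
#' @param params a [neuron_params()]
#' @param cfg a [meander_config()]
#' @param stimulus `"grid"` (default) or `"sinusoid"`
#' @param I_range_pA,G_range_nS calibration domain
#' @param n_I,n_G lattice resolution for the grid stimulus
#' @param segment_ms length of each constant-injection segment (ms)
#' @param settle_cycles probe cycles discarded at each segment start
#' @param quiescent_oversample length multiplier for the (0, 0) segment
#' @param duration_ms total length of the sinusoidal calibration (ms)
#' @param dt_ms control-loop step (ms)
#' @param form surface basis, see [fit_surfaces()]; the full quadratic by
#'   default
#' @param pulse_feature see [extract_features()]
#' @param ... further arguments to [make_calibration_signals()]
#'   (sinusoidal stimulus only)
#' @return a [calibration_surface()]
#' @export
calibrate_firing_clamp <- function(params, cfg,
                                   stimulus = c("grid", "sinusoid"),
                                   I_range_pA = c(0, 50),
                                   G_range_nS = c(0, 4),
                                   n_I = 6, n_G = 5, segment_ms = 120,
                                   settle_cycles = 8,
                                   quiescent_oversample = 8,
                                   duration_ms = 2000, dt_ms = 0.03,
                                   form = c("quadratic6", "bilinear4"),
                                   pulse_feature = "peak", ...) {
  stimulus <- match.arg(stimulus)
  form <- match.arg(form)
  if (stimulus == "sinusoid") {
    sig <- make_calibration_signals(I_range_pA = I_range_pA,
                                    G_range_nS = G_range_nS,
                                    duration_ms = duration_ms, dt_ms = dt_ms,
                                    probe_period_ms = 1000 / cfg$rate_Hz, ...)
    run <- run_firing_clamp(params, cfg, sig, duration_ms, dt_ms)
    feats <- extract_features(run$trace, run$markers,
                              pulse_feature = pulse_feature,
                              spike_threshold_mV = cfg$spike_threshold_mV)
    ctrl <- cycle_average_controls(sig, run$markers)
    return(fit_surfaces(feats, ctrl, form = form))
  }
  lattice <- expand.grid(I = seq(I_range_pA[1], I_range_pA[2], length.out = n_I),
                         G = seq(G_range_nS[1], G_range_nS[2], length.out = n_G))
  segs <- lapply(seq_len(nrow(lattice)), function(i) {
    seg <- segment_ms *
      if (lattice$I[i] == 0 && lattice$G[i] == 0) quiescent_oversample else 1
    n <- as.integer(round(seg / dt_ms))
    sig <- control_signals(dt_ms, rep(lattice$I[i], n), rep(lattice$G[i], n))
    run <- run_firing_clamp(params, cfg, sig, seg, dt_ms)
    f <- extract_features(run$trace, run$markers,
                          pulse_feature = pulse_feature,
                          spike_threshold_mV = cfg$spike_threshold_mV)
    keep <- f$qc == "ok"
    keep[seq_len(min(settle_cycles, length(keep)))] <- FALSE
    f[keep, , drop = FALSE]
  })
  ncyc <- vapply(segs, nrow, 0L)
  feats <- do.call(rbind, segs)
  feats$cycle <- seq_len(nrow(feats))
  feats$t_ms <- feats$cycle * 1000 / cfg$rate_Hz
  feats <- probe_features(feats)
  attr(feats, "pulse_feature") <- pulse_feature
  ctrl <- data.frame(cycle = feats$cycle,
                     I_pA = rep(lattice$I, ncyc), G_nS = rep(lattice$G, ncyc))
  fit_surfaces(feats, ctrl, form = form)
}
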