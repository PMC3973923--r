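#' Extract probe-spike features from a firing-clamp trace
#'
#' Measures, for every meander cycle, the two characteristics that carry
#' the synaptic information:
#' \describe{
#'   \item{V_pulse}{the positive-pulse response voltage.  The default
#'     `"peak"` convention reads the probe-spike amplitude: the maximum
#'     voltage from the pulse onset to `peak_margin_ms` past the pulse
#'     end.  It is robust to the sub-millisecond jitter of the spike peak
#'     around the pulse end, which under time-varying input contaminates
#'     point samples taken exactly at the pulse edge.  `"difference"`
#'     (voltage at pulse end minus voltage at pulse start) and
#'     `"absolute"` (voltage at pulse end) are available as alternatives;
#'     calibration and inversion always share one convention, so each is
#'     internally consistent;}
#'   \item{V_subthr}{the mean subthreshold potential over the zero-current
#'     segment of the cycle, from `settle_ms` after the negative pulse
#'     ends to the cycle end.}
#' }
#' Samples above `spike_threshold_mV` inside the averaging window
#' (spontaneous spikes) are excluded; a cycle loses its feature pair and is
#' flagged when the window is empty, more than `max_excluded_frac` of it is
#' spike-contaminated, or the cycle itself failed QC (no probe spike, or
#' the negative pulse hit its safety cap).
#'
#' @param trace a [voltage_trace()] from [run_firing_clamp()]
#' @param markers the matching cycle markers
#' @param settle_ms margin after the negative-pulse end before the
#'   averaging window opens (ms)
#' @param pulse_feature `"peak"` (default), `"difference"` or `"absolute"`
#' @param peak_margin_ms how far past the pulse end the `"peak"` search
#'   window extends (ms)
#' @param spike_threshold_mV spike criterion used to censor the averaging
#'   window (mV)
#' @param max_excluded_frac flag the cycle when more than this fraction of
#'   the window is censored
#' @return a `probe_features` data frame with columns `cycle`, `t_ms`
#'   (center of the averaging window), `Vsubthr_mV`, `Vpulse_mV`, `qc`
#'   (`"ok"` or a failure label)
#' @export
extract_features <- function(trace, markers, settle_ms = 0.5,
                             pulse_feature = c("peak", "difference",
                                               "absolute"),
                             peak_margin_ms = 1,
                             spike_threshold_mV = -20,
                             max_excluded_frac = 0.3) {
  pulse_feature <- match.arg(pulse_feature)
  stopifnot(inherits(trace, "voltage_trace"), nrow(markers) >= 1)
  dt <- trace$dt
  settle_steps <- as.integer(ceiling(settle_ms / dt))
  margin_steps <- as.integer(round(peak_margin_ms / dt))
  n <- nrow(markers)
  t_ms <- Vs <- Vp <- rep(NA_real_, n)
  qc <- rep("ok", n)
  for (j in seq_len(n)) {
    if (!is.na(markers$spike[j]) && !markers$spike[j]) qc[j] <- "no_spike"
    if (identical(markers$terminated_by[j], "cap")) qc[j] <- "neg_cap"
    Vp[j] <- switch(pulse_feature,
      peak = max(trace$V[markers$i_start[j]:
                           min(markers$i_pulse_end[j] + margin_steps,
                               length(trace$V))]),
      difference = trace$V[markers$i_pulse_end[j]] -
        trace$V[markers$i_start[j]],
      absolute = trace$V[markers$i_pulse_end[j]])
    lo <- markers$i_neg_end[j] + settle_steps
    hi <- markers$i_cycle_end[j]
    if (is.na(lo) || lo > hi) {
      qc[j] <- "no_window"
      next
    }
    win <- trace$V[lo:hi]
    keep <- win <= spike_threshold_mV
    if (mean(!keep) > max_excluded_frac) {
      if (qc[j] == "ok") qc[j] <- "contaminated"
      next
    }
    Vs[j] <- mean(win[keep])
    t_ms[j] <- trace$t0 + (mean(c(lo, hi)) - 1) * dt
  }
  out <- probe_features(data.frame(cycle = markers$cycle, t_ms = t_ms,
                                   Vsubthr_mV = Vs, Vpulse_mV = Vp, qc = qc))
  attr(out, "pulse_feature") <- pulse_feature
  out
}

#' Probe-feature series
#'
#' Light wrapper marking a data frame of per-cycle feature measurements
#' (columns `cycle`, `t_ms`, `Vsubthr_mV`, `Vpulse_mV`, `qc`).
#'
#' @param df a data frame with the columns above
#' @return the data frame with class `probe_features`
#' @export
probe_features <- function(df) {
  need <- c("cycle", "t_ms", "Vsubthr_mV", "Vpulse_mV", "qc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  ok <- df$qc == "ok"
  tt <- df$t_ms[ok]
  if (any(diff(tt) <= 0)) stop("feature times must be strictly increasing")
  structure(df, class = c("probe_features", "data.frame"))
}
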