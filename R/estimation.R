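#' Reversal potentials for the E/I decomposition
#'
#' @param V_E_mV excitatory reversal (mV); 0 mV for AMPA-type input
#' @param V_I_mV inhibitory reversal (mV), scalar or per-cycle vector for
#'   scenarios where V_I drifts (e.g. during prolonged GABA application);
#'   -74 mV default
#' @param V_0_mV resting membrane potential (mV)
#' @return object of class `reversal_spec`
#' @export
reversal_spec <- function(V_E_mV = 0, V_I_mV = -74, V_0_mV = -77) {
  if (any(abs(V_E_mV - V_I_mV) < 1)) {
    stop("|V_E - V_I| < 1 mV: the E/I decomposition is ill-conditioned")
  }
  structure(list(V_E = V_E_mV, V_I = V_I_mV, V_0 = V_0_mV),
            class = "reversal_spec")
}

#' Invert the calibration surfaces for one feature pair
#'
#' Solves the two-equation system `V_subthr = S_subthr(I, G)`,
#' `V_pulse = S_pulse(I, G)` for the injected current and conductance.
#' For the bilinear form, eliminating I reduces the system to a single
#' quadratic in G, solved in closed form.  Root selection: admissible
#' roots lie within the calibration domain expanded by `domain_margin`;
#' if both roots are admissible the one closer to `previous` (temporal
#' continuity) is taken, or closer to the domain center when no previous
#' estimate exists.  With no admissible root the status is `"failed"` and
#' the values are `NA` (never silently extrapolated).  For the
#' `quadratic6` form a damped Newton iteration is used, seeded from the
#' bilinear closed form, the previous estimate, and the domain center.
#'
#' @param surface a [calibration_surface()]
#' @param V_subthr_mV,V_pulse_mV measured features (scalars)
#' @param previous optional `c(I, G)` from the previous cycle
#' @param domain_margin admissibility margin as a fraction of the domain
#'   span
#' @return `list(I_pA, G_nS, status)` with status `"ok"` or `"failed"`
#' @export
invert_features <- function(surface, V_subthr_mV, V_pulse_mV,
                            previous = NULL, domain_margin = 0.5) {
  dom <- surface$domain
  span_I <- diff(dom$I_pA); span_G <- diff(dom$G_nS)
  lim_I <- dom$I_pA + c(-1, 1) * domain_margin * span_I
  lim_G <- dom$G_nS + c(-1, 1) * domain_margin * span_G
  center <- c(mean(dom$I_pA), mean(dom$G_nS))

  residual <- function(I, G) {
    v <- evaluate_surface(surface, I, G, warn_extrapolation = FALSE)
    max(abs(v$V_subthr_mV - V_subthr_mV), abs(v$V_pulse_mV - V_pulse_mV))
  }
  admissible <- function(I, G) {
    is.finite(I) && is.finite(G) &&
      I >= lim_I[1] && I <= lim_I[2] && G >= lim_G[1] && G <= lim_G[2]
  }
  pick <- function(cands) {
    ok <- Filter(function(c) admissible(c[1], c[2]) &&
                   residual(c[1], c[2]) < 1e-6, cands)
    if (length(ok) == 0)
      return(list(I_pA = NA_real_, G_nS = NA_real_, status = "failed"))
    if (length(ok) > 1) {
      ref <- if (!is.null(previous) && all(is.finite(previous))) previous
             else center
      d <- vapply(ok, function(c) ((c[1] - ref[1]) / span_I)^2 +
                    ((c[2] - ref[2]) / span_G)^2, 0)
      ok <- ok[order(d)]
    }
    list(I_pA = ok[[1]][1], G_nS = ok[[1]][2], status = "ok")
  }

  s <- surface$subthr; p <- surface$pulse
  if (surface$form == "bilinear4") {
    # Vs = a1 I G + b1 I + c1 G + d1 ; Vp = a2 I G + b2 I + c2 G + d2
    a1 <- s["a_IG"]; b1 <- s["a_I"]; c1 <- s["a_G"]; d1 <- s["a_0"]
    a2 <- p["a_IG"]; b2 <- p["a_I"]; c2 <- p["a_G"]; d2 <- p["a_0"]
    # eliminate I = (Vs - c1 G - d1) / (a1 G + b1):
    # (a2 G + b2)(Vs - c1 G - d1) = (Vp - c2 G - d2)(a1 G + b1)
    A <- a1 * c2 - a2 * c1
    B <- a2 * (V_subthr_mV - d1) - b2 * c1 - a1 * (V_pulse_mV - d2) + b1 * c2
    C <- b2 * (V_subthr_mV - d1) - b1 * (V_pulse_mV - d2)
    roots <- if (abs(A) < 1e-14) {
      if (abs(B) < 1e-14) numeric(0) else -C / B
    } else {
      disc <- B^2 - 4 * A * C
      if (disc < 0) numeric(0)
      else (-B + c(1, -1) * sqrt(disc)) / (2 * A)
    }
    cands <- lapply(roots, function(G) {
      den <- a1 * G + b1
      if (abs(den) < 1e-14) return(c(NA_real_, NA_real_))
      c(unname((V_subthr_mV - c1 * G - d1) / den), unname(G))
    })
    return(pick(cands))
  }

  # quadratic6: damped Newton from several starts
  newton <- function(x0) {
    x <- x0
    for (it in 1:60) {
      I <- x[1]; G <- x[2]
      f <- c(s["a_IG"] * I * G + s["a_I"] * I + s["a_G"] * G + s["a_0"] +
               s["a_II"] * I^2 + s["a_GG"] * G^2 - V_subthr_mV,
             p["a_IG"] * I * G + p["a_I"] * I + p["a_G"] * G + p["a_0"] +
               p["a_II"] * I^2 + p["a_GG"] * G^2 - V_pulse_mV)
      J <- rbind(c(s["a_IG"] * G + s["a_I"] + 2 * s["a_II"] * I,
                   s["a_IG"] * I + s["a_G"] + 2 * s["a_GG"] * G),
                 c(p["a_IG"] * G + p["a_I"] + 2 * p["a_II"] * I,
                   p["a_IG"] * I + p["a_G"] + 2 * p["a_GG"] * G))
      if (abs(det(J)) < 1e-14) return(c(NA_real_, NA_real_))
      step <- solve(J, f)
      # damp against leaving the admissible box wildly
      sc <- min(1, 2 * span_I / (abs(step[1]) + 1e-12),
                2 * span_G / (abs(step[2]) + 1e-12))
      x <- x - sc * step
      if (max(abs(f)) < 1e-9) break
    }
    x
  }
  starts <- list(center)
  if (!is.null(previous) && all(is.finite(previous)))
    starts <- c(list(previous), starts)
  blin <- invert_features(
    calibration_surface(s[1:4], p[1:4], dom, "bilinear4"),
    V_subthr_mV, V_pulse_mV, previous = previous,
    domain_margin = domain_margin)
  if (blin$status == "ok") starts <- c(list(c(blin$I_pA, blin$G_nS)), starts)
  pick(lapply(starts, newton))
}

#' Decompose (I, G) into excitatory and inhibitory conductances
#'
#' `G_E = (I - G (V_I - V_0)) / (V_E - V_I)` and `G_I = G - G_E`, so
#' `G = G_E + G_I` holds exactly by construction.  `V_I` may be a
#' per-cycle vector.  Negative results are reported as-is: clipping would
#' hide estimation error.
#'
#' @param I_pA,G_nS total synaptic current (pA, at rest) and conductance
#'   (nS); vectorized
#' @param rev a [reversal_spec()]
#' @return `list(G_E_nS, G_I_nS)`
#' @export
decompose_conductances <- function(I_pA, G_nS, rev) {
  stopifnot(inherits(rev, "reversal_spec"))
  G_E <- (I_pA - G_nS * (rev$V_I - rev$V_0)) / (rev$V_E - rev$V_I)
  list(G_E_nS = G_E, G_I_nS = G_nS - G_E)
}

#' Compose control signals from excitatory and inhibitory conductances
#'
#' The forward control-signal equations: `G = G_E + G_I` and
#' `I = G_E (V_E - V_0) + G_I (V_I - V_0)`.  Exact algebraic inverse of
#' [decompose_conductances()].
#'
#' @param G_E_nS,G_I_nS synaptic conductances (nS); vectorized
#' @param rev a [reversal_spec()]
#' @return `list(I_pA, G_nS)`
#' @export
compose_conductances <- function(G_E_nS, G_I_nS, rev) {
  stopifnot(inherits(rev, "reversal_spec"))
  if (any(G_E_nS < 0, na.rm = TRUE) || any(G_I_nS < 0, na.rm = TRUE))
    warning("negative synaptic conductance passed to compose_conductances()")
  list(I_pA = G_E_nS * (rev$V_E - rev$V_0) + G_I_nS * (rev$V_I - rev$V_0),
       G_nS = G_E_nS + G_I_nS)
}

#' Expected unclamped membrane voltage
#'
#' Conductance-weighted steady-state voltage
#' `V = (G_0 V_0 + G_E V_E + G_I V_I) / (G_0 + G_E + G_I)`: the voltage
#' the cell would settle at under the estimated synaptic input with no
#' injected current.
#'
#' @param G_0_nS resting input conductance (nS)
#' @param rev a [reversal_spec()]
#' @param G_E_nS,G_I_nS synaptic conductances (nS); vectorized
#' @return voltage (mV)
#' @export
reconstruct_voltage <- function(G_0_nS, rev, G_E_nS, G_I_nS) {
  stopifnot(inherits(rev, "reversal_spec"))
  den <- G_0_nS + G_E_nS + G_I_nS
  if (any(den <= 0, na.rm = TRUE))
    stop("nonpositive total conductance in reconstruct_voltage()")
  (G_0_nS * rev$V_0 + G_E_nS * rev$V_E + G_I_nS * rev$V_I) / den
}

#' Per-cycle synaptic conductance estimation
#'
#' The full single-trial analysis chain: extract the per-cycle features,
#' invert the calibration surfaces for (I, G), and decompose into
#' (G_E, G_I).  Cycles whose features are flagged or whose inversion fails
#' are carried through with `NA` values and an explanatory status.
#'
#' @param trace a [voltage_trace()] from [run_firing_clamp()]
#' @param markers the matching cycle markers
#' @param surface a fitted [calibration_surface()]
#' @param rev a [reversal_spec()]; `rev$V_I` may be a vector with one
#'   entry per cycle
#' @param ... passed to [extract_features()] (the `pulse_feature`
#'   convention defaults to the one the surface was fitted with)
#' @return an `estimate_series` data frame: `cycle`, `t_ms`,
#'   `Vsubthr_mV`, `Vpulse_mV`, `I_pA`, `G_nS`, `GE_nS`, `GI_nS`, `status`
#' @export
estimate_pipeline <- function(trace, markers, surface, rev, ...) {
  args <- list(...)
  if (is.null(args$pulse_feature)) args$pulse_feature <- surface$pulse_feature
  feats <- do.call(extract_features, c(list(trace, markers), args))
  n <- nrow(feats)
  I <- G <- rep(NA_real_, n)
  status <- feats$qc
  prev <- NULL
  for (j in seq_len(n)) {
    if (status[j] != "ok") next
    sol <- invert_features(surface, feats$Vsubthr_mV[j], feats$Vpulse_mV[j],
                           previous = prev)
    if (sol$status != "ok") {
      status[j] <- "inversion_failed"
      next
    }
    I[j] <- sol$I_pA; G[j] <- sol$G_nS
    prev <- c(sol$I_pA, sol$G_nS)
  }
  VIj <- if (length(rev$V_I) > 1) {
    if (length(rev$V_I) != n)
      stop("per-cycle V_I must have one entry per cycle (", n, ")")
    rev$V_I
  } else rep(rev$V_I, n)
  dec <- decompose_conductances(I, G, reversal_spec(rev$V_E, VIj, rev$V_0))
  out <- data.frame(cycle = feats$cycle, t_ms = feats$t_ms,
                    Vsubthr_mV = feats$Vsubthr_mV, Vpulse_mV = feats$Vpulse_mV,
                    I_pA = I, G_nS = G,
                    GE_nS = dec$G_E_nS, GI_nS = dec$G_I_nS, status = status)
  class(out) <- c("estimate_series", "data.frame")
  out
}
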