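test_that("sinusoidal calibration sweeps the I-G rectangle", {
  sig <- make_calibration_signals(periods_ms = c(40, 70),
                                  I_range_pA = c(0, 50), G_range_nS = c(0, 4),
                                  duration_ms = 4000, dt_ms = 0.03,
                                  probe_period_ms = NULL)
  # direct histogram oracle on per-cycle means (5 ms windows)
  steps <- as.integer(5 / 0.03)
  ncyc <- floor(length(sig$I) / steps)
  idx <- rep(seq_len(ncyc), each = steps)[seq_len(ncyc * steps)]
  Im <- tapply(sig$I[seq_along(idx)], idx, mean)
  Gm <- tapply(sig$G[seq_along(idx)], idx, mean)
  cells <- table(cut(Im, seq(min(Im), max(Im), length.out = 6)),
                 cut(Gm, seq(min(Gm), max(Gm), length.out = 6)))
  expect_true(all(cells >= 1))
  # conductance clipped at zero, never negative
  sig2 <- make_calibration_signals(G_range_nS = c(0, 4), duration_ms = 500,
                                   probe_period_ms = NULL)
  expect_gte(min(sig2$G), 0)
  # zero amplitude gives constant signals
  sig3 <- make_calibration_signals(I_range_pA = c(20, 20),
                                   G_range_nS = c(1, 1), duration_ms = 200,
                                   probe_period_ms = NULL)
  expect_equal(unique(sig3$I), 20)
  expect_equal(unique(sig3$G), 1)
  expect_warning(make_calibration_signals(periods_ms = c(40, 80),
                                          duration_ms = 200,
                                          probe_period_ms = NULL),
                 "commensurate")
  expect_error(make_calibration_signals(I_range_pA = c(50, 0)), "degenerate")
})

test_that("per-cycle control averages agree with closed-form window means", {
  s <- fc_setup()
  run <- fc_quiescent_run(1000)
  mk <- run$markers
  dt <- run$trace$dt
  n <- length(run$trace$V)
  # constant signals pass through
  cc <- cycle_average_controls(control_signals(dt, rep(7, n), rep(2, n)), mk)
  expect_equal(unique(cc$I_pA), 7)
  expect_equal(unique(cc$G_nS), 2)
  # a linear ramp averages to its mid-window value
  ramp <- seq(0, 100, length.out = n)
  cr <- cycle_average_controls(control_signals(dt, ramp, rep(0, n)), mk)
  mid <- (ramp[mk$i_start] + ramp[mk$i_cycle_end]) / 2
  expect_lt(max(abs(cr$I_pA - mid)), diff(ramp)[1] + 1e-9)
  # sinusoid: closed-form sum of the sampled sine over each window
  om <- 2 * pi / 40
  t <- (seq_len(n) - 1) * dt
  cs <- cycle_average_controls(control_signals(dt, sin(om * t), rep(0, n)), mk)
  exact <- vapply(seq_len(nrow(mk)), function(j) {
    k <- mk$i_start[j]:mk$i_cycle_end[j]
    # geometric-sum identity for sum of sin(om * t_k)
    m <- length(k); t0 <- (k[1] - 1) * dt
    Im(exp(1i * om * t0) * (exp(1i * om * m * dt) - 1) /
         (exp(1i * om * dt) - 1)) / m
  }, 0)
  expect_lt(max(abs(cs$I_pA - exact)), 1e-9)
})

test_that("fitting exact polynomial data recovers the printed coefficients", {
  surf0 <- fig1_surface()
  g <- expand.grid(I = seq(-50, 200, length.out = 6),
                   G = seq(0, 4, length.out = 5))
  v <- evaluate_surface(surf0, g$I, g$G)
  feats <- probe_features(data.frame(cycle = seq_len(nrow(g)),
                                     t_ms = 5 * seq_len(nrow(g)),
                                     Vsubthr_mV = v$V_subthr_mV,
                                     Vpulse_mV = v$V_pulse_mV, qc = "ok"))
  fit <- fit_surfaces(feats, data.frame(cycle = feats$cycle, I_pA = g$I,
                                        G_nS = g$G), form = "bilinear4")
  expect_equal(unname(fit$subthr), c(0.002, 0.079, 0.8, -76.8),
               tolerance = 1e-7)
  expect_equal(unname(fit$pulse), c(-0.0039, 0.0477, -0.49, -34.9),
               tolerance = 1e-7)
  # interpolation property: residuals at machine precision
  expect_lt(max(fit$residual_rms_mV), 1e-8)
})

test_that("coefficient estimates are unbiased under feature noise", {
  surf0 <- fig1_surface()
  g <- expand.grid(I = seq(-50, 200, length.out = 6),
                   G = seq(0, 4, length.out = 5))
  v <- evaluate_surface(surf0, g$I, g$G)
  set.seed(11)
  co <- replicate(100, {
    feats <- probe_features(data.frame(
      cycle = seq_len(nrow(g)), t_ms = 5 * seq_len(nrow(g)),
      Vsubthr_mV = v$V_subthr_mV + rnorm(nrow(g), 0, 0.5),
      Vpulse_mV = v$V_pulse_mV, qc = "ok"))
    fit_surfaces(feats, data.frame(cycle = feats$cycle, I_pA = g$I,
                                   G_nS = g$G), form = "bilinear4")$subthr
  })
  truth <- c(0.002, 0.079, 0.8, -76.8)
  err <- rowMeans(co) - truth
  se <- apply(co, 1, sd) / sqrt(ncol(co))
  expect_true(all(abs(err) < 3 * se + 1e-12))
})

test_that("a vanishing interaction term is recovered as zero", {
  g <- expand.grid(I = seq(-50, 200, length.out = 6),
                   G = seq(0, 4, length.out = 5))
  set.seed(12)
  y <- 0.1 * g$I + 0.9 * g$G - 70 + rnorm(nrow(g), 0, 0.3)
  feats <- probe_features(data.frame(cycle = seq_len(nrow(g)),
                                     t_ms = 5 * seq_len(nrow(g)),
                                     Vsubthr_mV = y, Vpulse_mV = y,
                                     qc = "ok"))
  fit <- fit_surfaces(feats, data.frame(cycle = feats$cycle, I_pA = g$I,
                                        G_nS = g$G), form = "bilinear4")
  # oracle standard error from the classical least-squares formula
  X <- cbind(g$I * g$G, g$I, g$G, 1)
  sig2 <- sum(lm.fit(X, y)$residuals^2) / (nrow(g) - 4)
  se <- sqrt(sig2 * solve(crossprod(X))[1, 1])
  expect_lt(abs(fit$subthr["a_IG"]), 3 * se)
})

test_that("surface evaluation matches the printed polynomials and is bilinear", {
  surf0 <- fig1_surface()
  at0 <- evaluate_surface(surf0, 0, 0)
  expect_equal(at0$V_subthr_mV, -76.8)
  expect_equal(at0$V_pulse_mV, -34.9)
  # hand arithmetic at (100 pA, 2 nS)
  at1 <- evaluate_surface(surf0, 100, 2)
  expect_equal(at1$V_subthr_mV, 0.002 * 200 + 0.079 * 100 + 0.8 * 2 - 76.8)
  # exactly linear in I at fixed G: second differences vanish
  vs <- evaluate_surface(surf0, c(0, 50, 100), 2)$V_subthr_mV
  expect_equal(diff(diff(vs)), 0)
  expect_warning(evaluate_surface(surf0, 500, 2), "outside")
})

test_that("the fuller basis never fits worse, and degeneracy is reported", {
  g <- expand.grid(I = seq(-50, 200, length.out = 6),
                   G = seq(0, 4, length.out = 5))
  set.seed(13)
  y <- 0.05 * g$I - 1.2 * g$G + 0.001 * g$I^2 - 60 + rnorm(nrow(g), 0, 0.2)
  feats <- probe_features(data.frame(cycle = seq_len(nrow(g)),
                                     t_ms = 5 * seq_len(nrow(g)),
                                     Vsubthr_mV = y, Vpulse_mV = y,
                                     qc = "ok"))
  ctrl <- data.frame(cycle = feats$cycle, I_pA = g$I, G_nS = g$G)
  f4 <- fit_surfaces(feats, ctrl, form = "bilinear4")
  f6 <- fit_surfaces(feats, ctrl, form = "quadratic6")
  expect_lte(f6$residual_rms_mV[1], f4$residual_rms_mV[1])
  # collinear design: all calibration points on one line in the I-G plane
  ctrl_bad <- data.frame(cycle = feats$cycle, I_pA = g$I, G_nS = g$I / 50)
  expect_error(fit_surfaces(feats, ctrl_bad, form = "bilinear4"),
               "rank-deficient")
})

test_that("grid calibration of the simulated neuron yields a tight surface", {
  s <- fc_setup()
  surf <- s$surface
  expect_s3_class(surf, "calibration_surface")
  expect_equal(surf$form, "quadratic6")
  expect_gt(surf$n_points, 400)
  expect_lt(surf$residual_rms_mV["subthr"], 0.5)
  expect_lt(surf$residual_rms_mV["pulse"], 1)
  # shunting sensitivity has the expected sign and scale
  expect_lt(surf$pulse[["a_G"]], -0.5)
  expect_gt(surf$subthr[["a_I"]], 0.05)
})
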