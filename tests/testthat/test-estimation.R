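test_that("inversion round-trips the forward surface to 1e-6", {
  surf0 <- fig1_surface()
  g <- expand.grid(I = seq(-40, 190, length.out = 7),
                   G = seq(0.1, 3.9, length.out = 7))
  v <- evaluate_surface(surf0, g$I, g$G, warn_extrapolation = FALSE)
  for (i in seq_len(nrow(g))) {
    sol <- invert_features(surf0, v$V_subthr_mV[i], v$V_pulse_mV[i])
    expect_equal(sol$status, "ok")
    expect_lt(abs(sol$I_pA - g$I[i]), 1e-6)
    expect_lt(abs(sol$G_nS - g$G[i]), 1e-6)
  }
  # the origin is a fixed point of the round trip
  v0 <- evaluate_surface(surf0, 0, 0)
  sol0 <- invert_features(surf0, v0$V_subthr_mV, v0$V_pulse_mV)
  expect_equal(c(sol0$I_pA, sol0$G_nS), c(0, 0), tolerance = 1e-8)
})

test_that("quadratic6 inversion round-trips through the Newton path", {
  s <- fc_setup()
  surf <- s$surface
  g <- expand.grid(I = seq(2, 48, length.out = 5), G = seq(0.1, 3.9, length.out = 5))
  v <- evaluate_surface(surf, g$I, g$G, warn_extrapolation = FALSE)
  for (i in seq_len(nrow(g))) {
    sol <- invert_features(surf, v$V_subthr_mV[i], v$V_pulse_mV[i])
    expect_equal(sol$status, "ok")
    expect_lt(abs(sol$I_pA - g$I[i]), 1e-5)
    expect_lt(abs(sol$G_nS - g$G[i]), 1e-6)
  }
})

test_that("a vanishing interaction reduces to the 2x2 linear system", {
  surf <- calibration_surface(
    subthr = c(a_IG = 0, a_I = 0.08, a_G = 0.8, a_0 = -76.8),
    pulse = c(a_IG = 0, a_I = 0.05, a_G = -0.5, a_0 = -34.9),
    domain = list(I_pA = c(-50, 200), G_nS = c(0, 4)))
  v <- evaluate_surface(surf, 120, 3)
  sol <- invert_features(surf, v$V_subthr_mV, v$V_pulse_mV)
  # linear-algebra oracle
  A <- rbind(c(0.08, 0.8), c(0.05, -0.5))
  x <- solve(A, c(v$V_subthr_mV + 76.8, v$V_pulse_mV + 34.9))
  expect_equal(c(sol$I_pA, sol$G_nS), unname(x), tolerance = 1e-9)
})

test_that("root selection follows continuity, then domain-center proximity", {
  # engineered surface with two admissible roots: Vs = I*G, Vp = I + G
  surf <- calibration_surface(
    subthr = c(a_IG = 1, a_I = 0, a_G = 0, a_0 = 0),
    pulse = c(a_IG = 0, a_I = 1, a_G = 1, a_0 = 0),
    domain = list(I_pA = c(0, 5.2), G_nS = c(0, 5)))
  # feature pair consistent with (I, G) = (1, 4) and (4, 1)
  near41 <- invert_features(surf, 4, 5, previous = c(3.8, 1.3))
  expect_equal(c(near41$I_pA, near41$G_nS), c(4, 1), tolerance = 1e-9)
  near14 <- invert_features(surf, 4, 5, previous = c(1.2, 3.7))
  expect_equal(c(near14$I_pA, near14$G_nS), c(1, 4), tolerance = 1e-9)
  # no previous estimate: the root closer to the domain center wins
  nocont <- invert_features(surf, 4, 5)
  expect_equal(c(nocont$I_pA, nocont$G_nS), c(4, 1), tolerance = 1e-9)
})

test_that("infeasible feature pairs fail loudly instead of extrapolating", {
  surf0 <- fig1_surface()
  sol <- invert_features(surf0, -76.8, 300)   # absurd pulse response
  expect_equal(sol$status, "failed")
  expect_true(is.na(sol$I_pA) && is.na(sol$G_nS))
})

test_that("compose and decompose are exact algebraic inverses", {
  rev <- reversal_spec(V_E_mV = 0, V_I_mV = -74, V_0_mV = -76.8)
  set.seed(3)
  GE <- runif(1000, 0, 10); GI <- runif(1000, 0, 10)
  cs <- compose_conductances(GE, GI, rev)
  dec <- decompose_conductances(cs$I_pA, cs$G_nS, rev)
  expect_lt(max(abs(dec$G_E_nS - GE)), 1e-10)
  expect_lt(max(abs(dec$G_I_nS - GI)), 1e-10)
  # pure inhibition: current equals G*(V_I - V_0)
  d <- decompose_conductances(2.5 * (rev$V_I - rev$V_0), 2.5, rev)
  expect_equal(d$G_E_nS, 0)
  expect_equal(d$G_I_nS, 2.5)
  expect_equal(decompose_conductances(0, 0, rev),
               list(G_E_nS = 0, G_I_nS = 0))
  # single-population limit
  cs1 <- compose_conductances(1.5, 0, rev)
  expect_equal(cs1$I_pA, 1.5 * (rev$V_E - rev$V_0))
  expect_equal(cs1$G_nS, 1.5)
  # worked example round trip
  cs2 <- compose_conductances(1, 2, rev)
  d2 <- decompose_conductances(cs2$I_pA, cs2$G_nS, rev)
  expect_equal(c(d2$G_E_nS, d2$G_I_nS), c(1, 2))
})

test_that("a drifting inhibitory reversal is honoured per cycle", {
  VI <- seq(-74, -60, length.out = 5)
  rev <- reversal_spec(V_E_mV = 0, V_I_mV = VI, V_0_mV = -77)
  GE <- rep(1, 5); GI <- rep(2, 5)
  cs <- compose_conductances(GE, GI, rev)
  expect_false(any(duplicated(cs$I_pA)))   # drift changes the composed current
  dec <- decompose_conductances(cs$I_pA, cs$G_nS, rev)
  expect_equal(dec$G_E_nS, GE, tolerance = 1e-12)
  expect_equal(dec$G_I_nS, GI, tolerance = 1e-12)
  expect_error(reversal_spec(V_I_mV = -0.5), "ill-conditioned")
})

test_that("voltage reconstruction is the conductance-weighted mean", {
  rev <- reversal_spec(V_E_mV = 0, V_I_mV = -74, V_0_mV = -76.8)
  expect_equal(reconstruct_voltage(1.5, rev, 0, 0), -76.8)
  expect_lt(abs(reconstruct_voltage(1.5, rev, 0, 1e6) - (-74)), 0.01)
  # arithmetic oracle
  expect_equal(reconstruct_voltage(1.5, rev, 1, 2),
               (1.5 * -76.8 + 1 * 0 + 2 * -74) / 4.5)
  expect_error(reconstruct_voltage(1.5, rev, -2, 0), "total conductance")
})

test_that("the pipeline reports near-zero conductances on quiescent input", {
  s <- fc_setup()
  run <- fc_quiescent_run(1000)
  est <- estimate_pipeline(run$trace, run$markers, s$surface, s$rev)
  expect_equal(nrow(est), nrow(run$markers))   # no silent drops
  ok <- est$status == "ok"
  expect_gt(mean(ok), 0.95)
  expect_lt(mean(abs(est$GE_nS[ok])), 0.1)
  expect_lt(mean(abs(est$GI_nS[ok])), 0.2)
  # negative excursions are preserved, not clipped
  expect_true(any(est$GE_nS[ok] < 0) || any(est$GI_nS[ok] < 0) ||
                all(abs(c(est$GE_nS[ok], est$GI_nS[ok])) < 0.2))
})

test_that("flagged cycles carry their status through the pipeline", {
  s <- fc_setup()
  n <- as.integer(200 / 0.03)
  sig <- control_signals(0.03, rep(0, n), rep(50, n))   # shunted: no spikes
  run <- run_firing_clamp(s$params, s$cfg, sig, 200)
  est <- estimate_pipeline(run$trace, run$markers, s$surface, s$rev)
  expect_equal(nrow(est), nrow(run$markers))
  expect_gt(sum(est$status != "ok"), nrow(est) / 2)
  expect_true(all(is.na(est$G_nS[est$status != "ok"])))
})
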