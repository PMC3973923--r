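# Direct enumeration oracle for the meander phase machine: given a
# scripted voltage sequence, write down the expected current at every step
# from the protocol definition alone.
enumerate_meander <- function(V_seq, cfg, dt) {
  period_steps <- round(1000 / cfg$rate_Hz / dt)
  pulse_steps <- round(cfg$tau_plus_ms / dt)
  cap_steps <- round(cfg$tau_minus_max_ms / dt)
  I <- numeric(length(V_seq))
  for (i in seq_along(V_seq)) {
    ph <- (i - 1) %% period_steps
    if (ph < pulse_steps) {
      I[i] <- cfg$I_plus_pA
    } else if (ph == pulse_steps) {
      I[i] <- cfg$I_minus_pA       # first negative step is unconditional
    } else {
      # negative phase persists until the first later sample at/below reset
      k0 <- i - ph + pulse_steps   # index of the first negative step
      ended <- FALSE
      for (k in (k0 + 1):i) {
        if (V_seq[k] <= cfg$V_reset_mV || (k - k0) >= cap_steps) {
          ended <- TRUE; break
        }
        if (k == i) break
      }
      I[i] <- if (ended) 0 else cfg$I_minus_pA
    }
  }
  I
}

test_that("meander state machine matches direct enumeration on scripted voltages", {
  cfg <- meander_config(rate_Hz = 100, tau_plus_ms = 1, tau_minus_max_ms = 4)
  dt <- 0.1
  set.seed(7)
  # scripted voltage wandering around the reset value
  V_seq <- -75 + cumsum(rnorm(300, 0, 1.5))
  expected <- enumerate_meander(V_seq, cfg, dt)
  ps <- NULL
  got <- vapply(seq_along(V_seq), function(i) {
    st <- meander_step((i - 1) * dt, V_seq[i], ps, cfg, dt)
    ps <<- st$phase_state
    st$I_pA
  }, 0)
  expect_equal(got, expected)
})

test_that("a voltage already below reset ends the negative pulse after one step", {
  cfg <- meander_config(rate_Hz = 100, tau_plus_ms = 1, tau_minus_max_ms = 4)
  dt <- 0.1
  V_seq <- rep(-90, 60)   # always below reset
  ps <- NULL
  got <- vapply(seq_along(V_seq), function(i) {
    st <- meander_step((i - 1) * dt, V_seq[i], ps, cfg, dt)
    ps <<- st$phase_state
    st$I_pA
  }, 0)
  # steps 1..10 positive, step 11 one negative step, then zero
  expect_equal(got[1:10], rep(cfg$I_plus_pA, 10))
  expect_equal(got[11], cfg$I_minus_pA)
  expect_equal(got[12:60], rep(0, 49))
})

test_that("dynamic-clamp law is I - G (V - V0)", {
  expect_equal(dynamic_clamp_current(50, 2, -77, -77), 50)
  expect_equal(dynamic_clamp_current(0, 1, -67, -77), -10)
  expect_equal(dynamic_clamp_current(82.4, 3, -77, -77), 82.4)
})

test_that("a 1 s quiescent run yields 200 probed cycles with clean resets", {
  run <- fc_quiescent_run(1000)
  mk <- run$markers
  cfg <- fc_setup()$cfg
  expect_equal(nrow(mk), 200)
  expect_true(all(mk$spike))
  expect_true(all(mk$terminated_by == "voltage_cross"))
  # positive-phase duration = tau_plus to within one control step
  expect_true(all(abs((mk$i_pulse_end - mk$i_start) * run$trace$dt -
                        cfg$tau_plus_ms) <= run$trace$dt))
  # termination voltage within [reset - 2, reset + 0.5]
  Vterm <- run$trace$V[mk$i_neg_end]
  expect_true(all(Vterm >= cfg$V_reset_mV - 2 & Vterm <= cfg$V_reset_mV + 0.5))
  # markers strictly ordered and non-overlapping
  expect_true(all(mk$i_start < mk$i_pulse_end &
                    mk$i_pulse_end < mk$i_neg_end &
                    mk$i_neg_end <= mk$i_cycle_end))
  expect_equal(mk$i_start[-1], head(mk$i_cycle_end, -1) + 1L)
})

test_that("cycle count is exactly floor(duration * rate / 1000)", {
  s <- fc_setup()
  for (dur in c(333, 502.5, 1000)) {
    run <- run_firing_clamp(s$params, s$cfg, NULL, dur, warmup_ms = 0)
    expect_equal(nrow(run$markers), floor(dur * s$cfg$rate_Hz / 1000))
  }
})

test_that("with G = 0 the dynamic clamp degenerates to a pure current source", {
  s <- fc_setup()
  n <- as.integer(300 / 0.03)
  sig <- control_signals(0.03, rep(25, n), rep(0, n))
  r1 <- run_firing_clamp(s$params, s$cfg, sig, 300, warmup_ms = 0)
  r2 <- run_firing_clamp(s$params, s$cfg, NULL, 300, I_hold_pA = 25,
                         warmup_ms = 0)
  expect_identical(r1$trace$V, r2$trace$V)
  expect_identical(r1$trace$I_inj, r2$trace$I_inj)
})

test_that("overwhelming shunt is flagged as spike failure, not mis-measured", {
  s <- fc_setup()
  n <- as.integer(200 / 0.03)
  sig <- control_signals(0.03, rep(0, n), rep(50, n))
  run <- run_firing_clamp(s$params, s$cfg, sig, 200)
  expect_gt(sum(!run$markers$spike), nrow(run$markers) / 2)
  f <- extract_features(run$trace, run$markers)
  expect_true(all(f$qc[!run$markers$spike] != "ok"))
})

test_that("the worked-example preset and config validation behave", {
  cfg <- meander_config(preset = "figure1")
  expect_equal(cfg$I_plus_pA, 400)
  expect_equal(cfg$I_minus_pA, -300)
  expect_equal(cfg$V_reset_mV, -80)
  expect_error(meander_config(I_minus_pA = 10))
  expect_error(meander_config(tau_minus_max_ms = 10))
  expect_error(control_signals(0.03, 1:5, c(-1, 1, 1, 1, 1)), "nonnegative")
})
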