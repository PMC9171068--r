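test_that("RMP is the 100 ms pre-step mean, with the below -80 mV indicator", {
  pr <- tiny_protocol(pre_step_s = 0.12)
  for (level in c(-78, -81.2, -79.9)) {
    rec <- make_rc_recording(pr, rmp_mV = level)
    r <- measure_rmp(rec)
    expect_equal(r$rmp_mV, level, tolerance = 1e-9)
    expect_identical(r$rmp_below_neg80, as.integer(level < -80))
  }
  # noisy baseline: equals the arithmetic mean of the exact window samples
  rec <- make_rc_recording(pr, rmp_mV = -80, noise_sd = 0.5, noise_seed = 3)
  sw <- stepclamp:::sweeps_at(rec, min(pr$amplitudes_pA))
  win <- stepclamp:::baseline_window(pr, 0.1)
  oracle <- mean(vapply(sw, function(s)
    mean(s$voltage_mV[s$time_s >= win[1] & s$time_s < win[2]]), numeric(1)))
  expect_equal(measure_rmp(rec)$rmp_mV, oracle, tolerance = 1e-12)

  short <- make_rc_recording(tiny_protocol(pre_step_s = 0.05))
  expect_error(measure_rmp(short),
               class = "stepclamp_insufficient_baseline_error")
})

test_that("voltage response is the steady-state deflection magnitude", {
  pr <- step_protocol(amplitudes_pA = c(-400, -100, 120), n_trials = 2)
  rec <- make_rc_recording(pr, R_MOhm = 100, tau_ms = 15, rmp_mV = -80)
  expect_equal(measure_voltage_response(rec, 120), 12, tolerance = 0.01)
  # -400 pA: baseline -80, steady -110 -> 30 mV at R = 75 MOhm
  rec2 <- make_rc_recording(pr, R_MOhm = 75, tau_ms = 15, rmp_mV = -80)
  expect_equal(measure_voltage_response(rec2, -400), 30, tolerance = 0.01)
  expect_error(measure_voltage_response(rec, 500),
               class = "stepclamp_protocol_error")
})

test_that("spike clipping reproduces the spike-free mean within 0.2 mV", {
  pr <- step_protocol(amplitudes_pA = 100, n_trials = 1)
  rec <- make_spiking_recording(pr, list("100" = c(0.3, 0.5, 0.75, 0.85)),
                                baseline_mV = -62, step_level_mV = -50)
  got <- measure_voltage_response(rec, 100)
  # masking oracle: drop every sample above spike threshold in the window
  s <- rec$sweeps[[1]]
  swin <- stepclamp:::steady_window(pr)
  sel <- s$time_s >= swin[1] & s$time_s < swin[2] & s$voltage_mV <= -45
  oracle <- abs(mean(s$voltage_mV[sel]) -
                mean(s$voltage_mV[s$time_s < 0.1 & s$time_s >= 0]))
  expect_equal(got, oracle, tolerance = 0.2)
})

test_that("input resistance converts the -100 pA deflection to MOhm", {
  pr <- tiny_protocol(amplitudes_pA = c(-100, 100), pre_step_s = 0.1,
                      step_dur_s = 0.8)
  # deflection 13.38 mV -> 133.8 MOhm (the wild-type median anchor)
  expect_equal(measure_input_resistance(
    make_rc_recording(pr, R_MOhm = 133.8, tau_ms = 5)), 133.8,
    tolerance = 0.05)
  expect_equal(measure_input_resistance(
    make_rc_recording(pr, R_MOhm = 100, tau_ms = 5)), 100, tolerance = 0.05)
  # simulated passive cell: 1000/gL oracle
  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -80, VT_mV = -50,
                     DeltaT_mV = 0)
  rec <- simulate_cell(p, step_protocol(amplitudes_pA = -100, n_trials = 1),
                       seed = 1)
  expect_equal(measure_input_resistance(rec), 125, tolerance = 2.5)
  noneg <- make_rc_recording(tiny_protocol(amplitudes_pA = c(-200, 100)))
  expect_error(measure_input_resistance(noneg),
               class = "stepclamp_protocol_error")
})

test_that("input resistance recovers 1000/gL within 2% across leak conductances", {
  pr <- step_protocol(amplitudes_pA = -100, n_trials = 1)
  for (gL in c(5, 7.5, 10, 15)) {
    p <- neuron_params(C_pF = 200, gL_nS = gL, EL_mV = -80, VT_mV = -50,
                       DeltaT_mV = 0)
    rec <- simulate_cell(p, pr, seed = 1)
    expect_lt(abs(measure_input_resistance(rec) - 1000 / gL) / (1000 / gL),
              0.02)
  }
})

test_that("the 67% crossing time equals 1.109 tau on ideal RC membranes", {
  pr <- tiny_protocol(amplitudes_pA = c(-100, 100), pre_step_s = 0.1,
                      step_dur_s = 0.8)
  for (tau in c(20, 30)) {
    rec <- make_rc_recording(pr, R_MOhm = 100, tau_ms = tau)
    expect_equal(measure_time_constant(rec, -100), tau * log(1 / 0.33),
                 tolerance = 0.3)
  }
  expect_error(measure_time_constant(rec, 100),
               class = "stepclamp_protocol_error")
  # sag barely perturbs the -100 pA crossing (within 10% of the gh = 0 twin)
  mk <- function(gh) simulate_cell(
    neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -50,
                  DeltaT_mV = 2, gh_nS = gh),
    step_protocol(amplitudes_pA = -100, n_trials = 1), seed = 1)
  t0 <- measure_time_constant(mk(0), -100)
  t1 <- measure_time_constant(mk(1.5), -100)
  expect_lt(abs(t1 - t0) / t0, 0.10)
})

test_that("sag decomposes into peak, steady state and normalized ratio", {
  # geometric fixture: baseline -80, trough -120, relaxation to steady -110
  pr <- step_protocol(amplitudes_pA = -400, n_trials = 1)
  t <- stepclamp:::protocol_time_grid(pr)
  on <- pr$pre_step_s; off <- on + pr$step_dur_s
  v <- ifelse(t < on, -80,
       ifelse(t < off, -110 - 10 * exp(-(t - on - 0.05)^2 / 2e-4) *
                         (t > on + 0.01), -80))
  v[t >= on & t <= on + 0.01] <- -80 - 40 * (t[t >= on & t <= on + 0.01] - on) / 0.01
  rec <- cell_recording("sagfix", "fix", pr, list(new_sweep(1, -400, t, v)))
  s <- measure_sag(rec)
  expect_equal(s$sag_mV, 10, tolerance = 0.05)
  expect_equal(s$response_mV, 30, tolerance = 0.05)
  expect_equal(s$sag_norm, 1 / 3, tolerance = 0.005)
  expect_false(s$qc_anomaly)

  # monotone in gh by paired simulation
  mk <- function(gh) simulate_cell(
    neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -50,
                  DeltaT_mV = 2, gh_nS = gh), pr, seed = 1)
  expect_gt(measure_sag(mk(1.5))$sag_norm, measure_sag(mk(0.5))$sag_norm)
})

test_that("passive features ignore voltage offsets and trial order", {
  pr <- tiny_protocol(amplitudes_pA = c(-400, -100), pre_step_s = 0.1,
                      step_dur_s = 0.8, n_trials = 3)
  rec <- make_rc_recording(pr, R_MOhm = 120, tau_ms = 25, rmp_mV = -80,
                           noise_sd = 0.2, noise_seed = 5)
  base <- measure_sag(rec)

  # uniform +7 mV offset leaves sag and its normalization untouched
  shifted <- rec
  shifted$sweeps <- lapply(shifted$sweeps, function(s) {
    s$voltage_mV <- s$voltage_mV + 7; s
  })
  s2 <- measure_sag(shifted)
  expect_equal(s2$sag_mV, base$sag_mV, tolerance = 1e-9)
  expect_equal(s2$sag_norm, base$sag_norm, tolerance = 1e-9)

  # trial permutation: relabel trials in reverse order
  perm <- rec
  perm$sweeps <- lapply(perm$sweeps, function(s) {
    s$trial_index <- pr$n_trials + 1L - s$trial_index; s
  })
  perm <- cell_recording(perm$cell_id, perm$group_label, pr, perm$sweeps)
  expect_equal(measure_input_resistance(perm), measure_input_resistance(rec),
               tolerance = 1e-12)
  expect_equal(measure_rmp(perm)$rmp_mV, measure_rmp(rec)$rmp_mV,
               tolerance = 1e-12)
  expect_equal(measure_sag(perm)$sag_norm, base$sag_norm, tolerance = 1e-12)
})
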