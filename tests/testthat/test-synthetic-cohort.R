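# protocol kept small where only single amplitudes are probed
one_step <- function(amps, pre = 0.1, n_trials = 1)
  step_protocol(amplitudes_pA = amps, pre_step_s = pre, n_trials = n_trials)

test_that("passive cell obeys Ohmic steady state and the RC 67% rule", {
  p <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                     DeltaT_mV = 0)
  rec <- simulate_cell(p, one_step(-100), seed = 1)
  # I/gL = 100 pA / 10 nS = 10 mV deflection -> V_ss = -90 mV
  expect_equal(measure_voltage_response(rec, -100), 10, tolerance = 0.005)
  avg <- stepclamp:::average_trace(rec, -100)
  steady <- stepclamp:::window_mean(avg$time_s, avg$voltage_mV,
                                    stepclamp:::steady_window(rec$protocol))
  expect_equal(steady, -90, tolerance = 0.05)
  # t67 = tau * ln(1/0.33), tau = C/gL = 20 ms
  expect_equal(measure_time_constant(rec, -100), 20 * log(1 / 0.33),
               tolerance = 0.3)
})

test_that("EIF cell fires at the first protocol step above its analytic rheobase", {
  p <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                     DeltaT_mV = 2)
  gt <- analytic_ground_truth(p)
  expect_equal(gt$rheobase_pA, 280)  # gL (VT - EL - DeltaT)
  rec <- simulate_cell(p, one_step(c(200, 300)), seed = 1)
  counts <- count_aps(rec)
  expect_identical(counts$ap_count[counts$amplitude_pA == 200], 0)
  expect_gte(counts$ap_count[counts$amplitude_pA == 300], 1)
})

test_that("analytic ground truth matches its closed forms", {
  gt <- analytic_ground_truth(neuron_params(gL_nS = 7.474, C_pF = 200,
                                            EL_mV = -80, VT_mV = -50))
  expect_equal(gt$Rin_MOhm, 1000 / 7.474, tolerance = 1e-12)  # 133.8 MOhm
  gt2 <- analytic_ground_truth(neuron_params(gL_nS = 10, C_pF = 200))
  expect_equal(gt2$tau_ms, 20)
  expect_false(gt2$has_sag)
})

test_that("numeric rheobase brackets the analytic value and responds to adaptation", {
  base <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                        DeltaT_mV = 2)
  nr <- numeric_rheobase(base, tol_pA = 0.5)
  expect_lt(abs(nr - 280), 0.5 + 5)  # finite-duration margin
  witha <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                         DeltaT_mV = 2, a_nS = 2)
  expect_gt(numeric_rheobase(witha, tol_pA = 0.5), nr)
  # sag regime: finite and self-consistent across tolerance settings
  withh <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                         DeltaT_mV = 2, gh_nS = 2, a_nS = 1)
  r1 <- numeric_rheobase(withh, tol_pA = 1)
  r2 <- numeric_rheobase(withh, tol_pA = 0.1)
  expect_lt(abs(r1 - r2), 1.1)
  expect_error(
    numeric_rheobase(base, upper_pA = 100),
    class = "stepclamp_unbounded_error")
})

test_that("halving the integration step barely moves voltages or spike times", {
  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                     DeltaT_mV = 2, a_nS = 1, b_pA = 20, gh_nS = 1.5)
  pr <- one_step(c(-400, -100, 300))
  r1 <- simulate_cell(p, pr, seed = 1, dt_ms = 0.05)
  r2 <- simulate_cell(p, pr, seed = 1, dt_ms = 0.025)
  for (amp in c(-400, -100)) {  # subthreshold sweeps: pointwise bound
    v1 <- stepclamp:::average_trace(r1, amp)$voltage_mV
    v2 <- stepclamp:::average_trace(r2, amp)$voltage_mV
    expect_lt(max(abs(v1 - v2)), 0.1)
  }
  s1 <- spike_log(r1); s2 <- spike_log(r2)
  expect_identical(nrow(s1), nrow(s2))
  # the first threshold crossing is step-size-converged; later spikes pick
  # up a slow phase drift along the train, so the tight bound applies to
  # the train onset
  expect_lt(abs(s1$spike_time_s[1] - s2$spike_time_s[1]), 2e-4)
})

test_that("sag grows monotonically with the H-conductance and vanishes without it", {
  mk <- function(gh) {
    p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -50,
                       DeltaT_mV = 2, gh_nS = gh)
    simulate_cell(p, one_step(-400), seed = 1)
  }
  sags <- vapply(c(0, 0.5, 1, 2), function(g) measure_sag(mk(g))$sag_mV,
                 numeric(1))
  expect_true(all(diff(sags) >= 0))
  expect_lt(measure_sag(mk(0))$sag_norm, 0.02)
})

test_that("cohort generation is deterministic and complete", {
  pr <- tiny_protocol(amplitudes_pA = c(-100, 100), pre_step_s = 0.1)
  spec <- cohort_spec(n_cells = 2, seed = 9, protocol = pr)
  c1 <- generate_cohort(spec, compute_rheobase = FALSE)
  c2 <- generate_cohort(spec, compute_rheobase = FALSE)
  expect_identical(nrow(c1$ground_truth), 4L)  # 2 groups x 2 cells
  expect_identical(c1$ground_truth, c2$ground_truth)
  for (i in seq_along(c1$recordings))
    for (k in seq_along(c1$recordings[[i]]$sweeps))
      expect_identical(c1$recordings[[i]]$sweeps[[k]]$voltage_mV,
                       c2$recordings[[i]]$sweeps[[k]]$voltage_mV)
  # byte-identical bundles on disk
  p1 <- withr::local_tempdir(); p2 <- withr::local_tempdir()
  write_sweep_bundle(c1$recordings, p1)
  write_sweep_bundle(c2$recordings, p2)
  expect_identical(unname(tools::md5sum(file.path(p1, "sweeps.csv"))),
                   unname(tools::md5sum(file.path(p2, "sweeps.csv"))))
})

test_that("unsatisfiable truncation and invalid parameters are refused", {
  expect_error(param_dist(0, 1, 5, 4), class = "stepclamp_spec_error")
  bad <- wt_like_regime()
  bad$gL_nS <- param_dist(6, 0.1, 50, 60)  # truncation far outside support
  spec <- cohort_spec(groups = list(g = bad), n_cells = 1, seed = 1,
                      protocol = tiny_protocol())
  expect_error(generate_cohort(spec), class = "stepclamp_spec_error")
  expect_error(neuron_params(Vreset_mV = -40, VT_mV = -50),
               class = "stepclamp_validation_error")
})
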