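ap_protocol <- function(amps = 100, n_trials = 1)
  step_protocol(amplitudes_pA = amps, n_trials = n_trials)

test_that("detector finds inserted APs and nothing on flat traces", {
  pr <- ap_protocol()
  t <- stepclamp:::protocol_time_grid(pr)
  flat <- detect_spikes(rep(-70, length(t)), t)
  expect_identical(nrow(flat), 0L)

  rec <- make_spiking_recording(pr, list("100" = c(0.2, 0.4, 0.6)))
  tr <- detect_spikes(rec$sweeps[[1]]$voltage_mV, rec$sweeps[[1]]$time_s)
  expect_identical(nrow(tr), 3L)
  expect_lt(max(abs(tr$peak_time_s - c(0.2, 0.4, 0.6))), 1e-4)
  expect_true(all(tr$threshold_time_s < tr$peak_time_s))
  expect_true(all(tr$threshold_mV < tr$peak_mV))
  expect_true(all(diff(tr$peak_time_s) > 0))
})

test_that("detector agrees with the simulator's own spike event log", {
  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                     DeltaT_mV = 2, a_nS = 1, b_pA = 20, gh_nS = 1.5)
  rec <- simulate_cell(p, ap_protocol(c(200, 300), n_trials = 2), seed = 4)
  log <- spike_log(rec)
  for (amp in c(200, 300)) {
    counts <- count_aps(rec)
    want <- nrow(log[log$amplitude_pA == amp & log$trial == 1, ])
    expect_identical(counts$ap_count[counts$amplitude_pA == amp],
                     as.numeric(want))
  }
})

test_that("detector is invariant to time shifts and voltage offsets", {
  det <- spike_detector(peak_floor_mV = -Inf)
  pr <- ap_protocol()
  rec <- make_spiking_recording(pr, list("100" = c(0.3, 0.5)))
  s <- rec$sweeps[[1]]
  tr0 <- detect_spikes(s$voltage_mV, s$time_s, det)
  tr_shift <- detect_spikes(s$voltage_mV + 40, s$time_s + 2.5, det)
  expect_identical(nrow(tr_shift), nrow(tr0))
  expect_equal(tr_shift$peak_time_s, tr0$peak_time_s + 2.5, tolerance = 1e-9)
  expect_equal(tr_shift$threshold_mV, tr0$threshold_mV + 40, tolerance = 1e-9)
})

test_that("rheobase is the per-trial minimum firing step, averaged", {
  pr <- ap_protocol(c(100, 200, 300, 400), n_trials = 3)
  # counts {100:0, 200:0, 300:2, 400:5} in all trials -> 300
  sched <- list("100" = numeric(0), "200" = numeric(0),
                "300" = c(0.3, 0.5), "400" = c(0.2, 0.3, 0.4, 0.5, 0.6))
  rec <- make_spiking_recording(pr, sched)
  expect_equal(measure_rheobase(rec), 300)

  # trials fire first at 200, 300, 300 -> mean 266.7
  sched2 <- list(
    "100" = list(numeric(0), numeric(0), numeric(0)),
    "200" = list(c(0.3), numeric(0), numeric(0)),
    "300" = list(c(0.3), c(0.3), c(0.3)),
    "400" = list(c(0.3), c(0.3), c(0.3)))
  rec2 <- make_spiking_recording(pr, sched2)
  expect_equal(measure_rheobase(rec2), mean(c(200, 300, 300)))

  silent <- make_spiking_recording(pr, list("100" = numeric(0),
    "200" = numeric(0), "300" = numeric(0), "400" = numeric(0)))
  r <- measure_rheobase(silent)
  expect_true(is.na(r))
  expect_true(attr(r, "nonfiring"))

  # EIF cell with analytic rheobase 280 pA lands on the 300 pA step
  p <- neuron_params(C_pF = 200, gL_nS = 10, EL_mV = -80, VT_mV = -50,
                     DeltaT_mV = 2)
  rec3 <- simulate_cell(p, pr, seed = 1)
  expect_equal(measure_rheobase(rec3), 300)
})

test_that("AP threshold is read from the first spike and normalized to RMP", {
  pr <- ap_protocol(c(100, 200))
  rec <- make_spiking_recording(pr, list("100" = numeric(0), "200" = 0.4))
  thr <- ap_threshold(rec, rmp_mV = -80)
  expect_equal(thr$threshold_mV, -45, tolerance = 0.5)
  expect_equal(thr$threshold_rel_mV, -45 - (-80), tolerance = 0.5)

  # on AdEx cells the dV/dt-detected threshold sits above VT by about
  # DeltaT * log(dvdt_thresh * C / (gL * DeltaT)) (where the exponential
  # current first dominates the commanded dV/dt)
  for (seed in 1:3) {
    p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                       DeltaT_mV = 2, a_nS = 1, b_pA = 20)
    rec <- simulate_cell(p, ap_protocol(c(200, 300)), seed = seed)
    got <- ap_threshold(rec, rmp_mV = -79)$threshold_mV
    bound <- p$DeltaT_mV *
      log(20 * p$C_pF / (p$gL_nS * p$DeltaT_mV))
    expect_gt(got, p$VT_mV - 1)
    expect_lt(got, p$VT_mV + bound + 3)
  }
})

test_that("waveform morphometrics match the fixture geometry", {
  pr <- ap_protocol(100)
  rec <- make_spiking_recording(pr, list("100" = 0.4), step_level_mV = -50)
  wf <- ap_waveform(rec)
  dt_ms <- 0.1  # one sample period at 10 kHz
  expect_equal(wf$amplitude_mV, 80, tolerance = 0.5)
  expect_equal(wf$halfwidth_ms, 0.75, tolerance = dt_ms)
  expect_equal(wf$rise_ms, 0.8 * 0.5, tolerance = dt_ms)
  expect_equal(wf$decay_ms, 0.8 * 1.0, tolerance = dt_ms)
  expect_equal(wf$ahp_mV, -45 - (-52), tolerance = 0.5)
})

test_that("f-I counts average trials and increase with drive", {
  pr <- ap_protocol(c(100, 200), n_trials = 3)
  sched <- list(
    "100" = list(numeric(0), numeric(0), numeric(0)),
    "200" = list(c(0.2, 0.3, 0.4, 0.5), c(0.2, 0.3, 0.4, 0.5, 0.6),
                 c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)))
  rec <- make_spiking_recording(pr, sched)
  fi <- count_aps(rec)
  expect_equal(fi$ap_count, c(0, 5))  # (4+5+6)/3 = 5

  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                     DeltaT_mV = 2, a_nS = 1, b_pA = 15)
  sim <- simulate_cell(p, ap_protocol(seq(100, 900, by = 100)), seed = 2)
  counts <- count_aps(sim)$ap_count
  expect_true(all(diff(counts) >= 0))  # no depolarization block in range
})

test_that("firing probability summarizes per-cell indicators as k/n", {
  pr <- ap_protocol(100, n_trials = 3)
  fire <- make_spiking_recording(pr, list("100" = c(0.3, 0.5)))
  mute <- make_spiking_recording(pr, list("100" = numeric(0)))
  cells <- c(replicate(9, fire, simplify = FALSE),
             replicate(13, mute, simplify = FALSE))
  fp <- firing_probability(cells, 100)
  expect_identical(fp$summary$k, 9L)
  expect_equal(fp$summary$percent, 100 * 9 / 22)
  expect_equal(firing_probability(replicate(5, fire, simplify = FALSE),
                                  100)$summary$fraction, 1)

  # majority rule: firing in 1 of 3 trials is not enough, 2 of 3 is
  one_of_three <- make_spiking_recording(pr, list(
    "100" = list(c(0.3), numeric(0), numeric(0))))
  two_of_three <- make_spiking_recording(pr, list(
    "100" = list(c(0.3), c(0.3), numeric(0))))
  expect_identical(cell_fired(one_of_three, 100), 0L)
  expect_identical(cell_fired(two_of_three, 100), 1L)
  expect_identical(cell_fired(one_of_three, 100, rule = "any"), 1L)
})

test_that("delay to first spike counts from step onset", {
  pr <- ap_protocol(100)
  for (d in c(0.150, 0.230)) {
    rec <- make_spiking_recording(pr, list("100" = pr$pre_step_s + d))
    expect_equal(delay_to_first_spike(rec, 100), d, tolerance = 1e-4)
  }
  expect_true(is.na(delay_to_first_spike(
    make_spiking_recording(pr, list("100" = numeric(0))), 100)))

  # delay shrinks as the drive rises above rheobase
  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                     DeltaT_mV = 2, a_nS = 1, b_pA = 15)
  sim <- simulate_cell(p, ap_protocol(c(200, 300, 400)), seed = 2)
  dd <- vapply(c(200, 300, 400), function(a)
    delay_to_first_spike(sim, a), numeric(1))
  expect_true(all(diff(dd) < 0))
})

test_that("instantaneous frequencies are reciprocal interspike intervals", {
  expect_equal(instantaneous_frequencies(c(0, 0.010, 0.030)), c(100, 50))
  expect_equal(instantaneous_frequencies(seq(0, by = 0.025, length.out = 9)),
               rep(40, 8))
  expect_length(instantaneous_frequencies(0.3), 0)

  # adaptation makes every simulated train decelerate
  p <- neuron_params(C_pF = 200, gL_nS = 8, EL_mV = -79, VT_mV = -55,
                     DeltaT_mV = 2, a_nS = 1, b_pA = 20)
  sim <- simulate_cell(p, ap_protocol(c(300, 400)), seed = 6)
  for (amp in c(300, 400)) {
    f <- stepclamp:::inst_freq_at(sim, amp)
    expect_gt(f[1], f[length(f)])
  }
})

test_that("accommodation summary collapses the late interval range", {
  expect_equal(accommodation_summary(rep(100, 25))$late_mean_Hz, 100)
  f <- 100 * 0.9^(0:24)
  oracle <- mean(f[15:20])  # direct summation over the printed range
  expect_equal(accommodation_summary(f, c(15, 20))$late_mean_Hz, oracle)
  expect_equal(accommodation_summary(f, c(15, 20))$f2, 90)
  short <- accommodation_summary(100 * 0.9^(0:8), c(15, 20))
  expect_true(is.na(short$late_mean_Hz))
  expect_false(is.na(short$f3))
})
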