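# Fixtures and independent oracles shared across the suite.
# Everything here is built in code; nothing touches the simulator unless
# stated, so these can serve as independent checks of it.

# small, fast protocol for structural / IO tests
tiny_protocol <- function(amplitudes_pA = c(-100, 100), n_trials = 2,
                          pre_step_s = 0.02, step_dur_s = 0.05,
                          post_step_s = 0.01, sampling_rate_hz = 10000) {
  step_protocol(amplitudes_pA = amplitudes_pA, pre_step_s = pre_step_s,
                step_dur_s = step_dur_s, post_step_s = post_step_s,
                n_trials = n_trials, sampling_rate_hz = sampling_rate_hz)
}

# analytic RC-membrane recording: V = rmp + I*R*(1 - exp(-t/tau)) during the
# step, exponential relaxation afterwards; no simulator involved
make_rc_recording <- function(protocol = step_protocol(),
                              R_MOhm = 100, tau_ms = 20, rmp_mV = -80,
                              cell_id = "rc", group_label = "fix",
                              noise_sd = 0, noise_seed = NULL, ...) {
  t <- stepclamp:::protocol_time_grid(protocol)
  on <- protocol$pre_step_s
  off <- on + protocol$step_dur_s
  tau_s <- tau_ms / 1000
  sweeps <- list()
  if (!is.null(noise_seed)) set.seed(noise_seed)
  for (amp in protocol$amplitudes_pA) {
    vinf <- amp * R_MOhm / 1000  # pA * MOhm = uV*1e3 -> mV deflection
    v_step_end <- vinf * (1 - exp(-(off - on) / tau_s))
    v <- ifelse(t < on, 0,
         ifelse(t < off, vinf * (1 - exp(-(t - on) / tau_s)),
                v_step_end * exp(-(t - off) / tau_s))) + rmp_mV
    for (trial in seq_len(protocol$n_trials)) {
      vt <- v
      if (noise_sd > 0) vt <- vt + rnorm(length(v), 0, noise_sd)
      sweeps[[length(sweeps) + 1L]] <- new_sweep(trial, amp, t, vt)
    }
  }
  cell_recording(cell_id, group_label, protocol, sweeps, ...)
}

# parametric AP shape: slow 5 ms ramp baseline->threshold (5 mV/ms), linear
# rise threshold->peak over rise_ms, linear decay peak->threshold over
# decay_ms, linear dip to trough over 2 ms, then exponential return.
# Returns the voltage waveform to add sample-by-sample at an insertion point.
ap_shape <- function(fs_hz = 10000, baseline_mV = -70, threshold_mV = -45,
                     peak_mV = 35, rise_ms = 0.5, decay_ms = 1.0,
                     trough_mV = -52) {
  dt_ms <- 1000 / fs_hz
  ramp <- seq(baseline_mV, threshold_mV, by = 5 * dt_ms)
  rise <- seq(threshold_mV, peak_mV,
              length.out = round(rise_ms / dt_ms) + 1L)[-1]
  decay <- seq(peak_mV, threshold_mV,
               length.out = round(decay_ms / dt_ms) + 1L)[-1]
  dip <- seq(threshold_mV, trough_mV, length.out = round(2 / dt_ms) + 1L)[-1]
  rec <- trough_mV + (baseline_mV - trough_mV) *
    (1 - exp(-(1:round(20 / dt_ms)) * dt_ms / 5))
  c(ramp, rise, decay, dip, rec)
}

# recording with AP shapes pasted onto a flat trace at given peak times;
# `step_level_mV` (default = baseline) sets the plateau during the step epoch
make_spiking_recording <- function(protocol, spike_peak_times_by_amp,
                                   baseline_mV = -70,
                                   step_level_mV = baseline_mV,
                                   fs_args = list(),
                                   cell_id = "apfix", group_label = "fix") {
  t <- stepclamp:::protocol_time_grid(protocol)
  fs <- protocol$sampling_rate_hz
  shape <- do.call(ap_shape, c(list(fs_hz = fs, baseline_mV = step_level_mV),
                               fs_args))
  peak_off <- which.max(shape) - 1L  # samples from shape start to peak
  in_step <- t >= protocol$pre_step_s &
    t < protocol$pre_step_s + protocol$step_dur_s
  sweeps <- list()
  for (amp in protocol$amplitudes_pA) {
    key <- as.character(amp)
    per_trial <- spike_peak_times_by_amp[[key]]
    for (trial in seq_len(protocol$n_trials)) {
      v <- rep(baseline_mV, length(t))
      v[in_step] <- step_level_mV
      times <- if (is.list(per_trial)) per_trial[[trial]] else per_trial
      for (pt in times) {
        i0 <- round(pt * fs) + 1L - peak_off
        idx <- i0:(i0 + length(shape) - 1L)
        keep <- idx >= 1 & idx <= length(v)
        v[idx[keep]] <- shape[keep]
      }
      sweeps[[length(sweeps) + 1L]] <- new_sweep(trial, amp, t, v)
    }
  }
  cell_recording(cell_id, group_label, protocol, sweeps)
}

# --- independent statistical oracles ---------------------------------------

# exact two-sided Mann-Whitney p by full enumeration over all
# C(nx+ny, nx) rank splits (tie-free data only)
mwu_enumeration_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # U of x over y
  splits <- utils::combn(nx + ny, nx)
  r_sorted <- rank(pooled)  # ranks are 1..N for tie-free data
  w_null <- apply(splits, 2, function(ix) sum(r_sorted[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(w_null <= w_obs)
  p_ge <- mean(w_null >= w_obs)
  list(U = min(w_obs, nx * ny - w_obs), p = min(1, 2 * min(p_le, p_ge)))
}

# Grubbs critical value straight from the t-quantile formula
grubbs_crit_oracle <- function(n, alpha = 0.05) {
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}
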