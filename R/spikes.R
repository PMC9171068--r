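#' Spike detector configuration
#'
#' Detection criteria for action potentials on a voltage trace. A spike is
#' a local maximum at or above `peak_floor_mV` that is preceded within
#' `search_ms` by a depolarization rate of at least
#' `dvdt_thresh_mV_per_ms`; accepted peaks are separated by at least
#' `min_isi_ms`. The threshold point of a spike is the first sample of the
#' sustained dV/dt run leading into the peak. `peak_floor_mV = -Inf`
#' disables the absolute-peak criterion, leaving a purely rate-based
#' (voltage-offset-invariant) detector.
#'
#' @param dvdt_thresh_mV_per_ms upstroke rate criterion (mV/ms).
#' @param peak_floor_mV minimum absolute peak voltage.
#' @param min_isi_ms minimum inter-peak interval.
#' @param search_ms how far before a peak the upstroke may start.
#' @param ahp_window_ms afterhyperpolarization search window after a peak.
#' @return An object of class `spike_detector`.
#' @export
spike_detector <- function(dvdt_thresh_mV_per_ms = 20, peak_floor_mV = -10,
                           min_isi_ms = 1, search_ms = 5,
                           ahp_window_ms = 50) {
  structure(list(dvdt_thresh_mV_per_ms = dvdt_thresh_mV_per_ms,
                 peak_floor_mV = peak_floor_mV, min_isi_ms = min_isi_ms,
                 search_ms = search_ms, ahp_window_ms = ahp_window_ms),
            class = "spike_detector")
}

#' Detect action potentials on one trace
#'
#' @param voltage_mV,time_s one sweep's samples (uniform grid).
#' @param detector a [spike_detector()].
#' @return A `spike_train` data frame with one row per spike:
#'   `peak_time_s`, `peak_mV`, `threshold_time_s`, `threshold_mV`,
#'   `peak_index`, `threshold_index`. An empty train is a valid result.
#' @export
detect_spikes <- function(voltage_mV, time_s, detector = spike_detector()) {
  n <- length(voltage_mV)
  empty <- data.frame(peak_time_s = numeric(), peak_mV = numeric(),
                      threshold_time_s = numeric(), threshold_mV = numeric(),
                      peak_index = integer(), threshold_index = integer())
  class(empty) <- c("spike_train", "data.frame")
  if (n < 3) return(empty)

  dt_ms <- 1000 * (time_s[2] - time_s[1])
  dvdt <- diff(voltage_mV) / dt_ms        # dvdt[i]: slope from sample i to i+1
  search_n <- max(1L, as.integer(round(detector$search_ms / dt_ms)))

  v <- voltage_mV
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_peak & v >= detector$peak_floor_mV)

  fast <- dvdt >= detector$dvdt_thresh_mV_per_ms
  peaks <- integer(0)
  thr_idx <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    lo <- max(1L, i - search_n)
    win <- fast[lo:(i - 1L)]
    if (!any(win)) next
    if ((time_s[i] - last_t) * 1000 < detector$min_isi_ms) next
    # threshold: first sample of the contiguous fast-upstroke run before the peak
    j <- max(which(win)) + lo - 1L
    while (j > 1L && fast[j - 1L]) j <- j - 1L
    peaks <- c(peaks, i)
    thr_idx <- c(thr_idx, j)
    last_t <- time_s[i]
  }
  out <- if (length(peaks) > 0)
    data.frame(peak_time_s = time_s[peaks], peak_mV = v[peaks],
               threshold_time_s = time_s[thr_idx], threshold_mV = v[thr_idx],
               peak_index = peaks, threshold_index = thr_idx)
  else empty
  class(out) <- c("spike_train", "data.frame")
  out
}

#' Attach a spike-train cache to a recording
#'
#' Spike detection is the inner loop of feature extraction; most measures
#' revisit the same sweeps. This memoizes [detect_spikes()] per
#' (amplitude, trial) on the recording so each sweep is scanned once. All
#' extraction functions consult the cache automatically when the detector
#' matches; [extract_features()] attaches it for you.
#'
#' @param rec a [cell_recording()].
#' @param detector the [spike_detector()] the cache is valid for.
#' @return `rec` with a lazy cache attached.
#' @export
cache_spikes <- function(rec, detector = spike_detector()) {
  attr(rec, "spike_cache") <- new.env(parent = emptyenv())
  attr(rec, "spike_cache_detector") <- detector
  rec
}

# full-sweep train, via the recording's cache when present and valid
cached_train <- function(rec, sweep, detector) {
  cache <- attr(rec, "spike_cache")
  if (is.null(cache) ||
      !identical(attr(rec, "spike_cache_detector"), detector))
    return(detect_spikes(sweep$voltage_mV, sweep$time_s, detector))
  key <- paste(sweep$amplitude_pA, sweep$trial_index)
  tr <- cache[[key]]
  if (is.null(tr)) {
    tr <- detect_spikes(sweep$voltage_mV, sweep$time_s, detector)
    assign(key, tr, envir = cache)
  }
  tr
}

# spikes of one sweep, optionally restricted to the stimulus epoch
sweep_spike_train <- function(rec, sweep, detector, step_only = TRUE) {
  tr <- cached_train(rec, sweep, detector)
  if (step_only && nrow(tr) > 0) {
    p <- rec$protocol
    on <- p$pre_step_s
    off <- p$pre_step_s + p$step_dur_s
    tr <- tr[tr$peak_time_s >= on & tr$peak_time_s < off, , drop = FALSE]
  }
  tr
}

#' Rheobase from a recording
#'
#' Minimum depolarizing step amplitude evoking at least one action
#' potential during the stimulus epoch. Spike detection is per trial; the
#' per-trial minima are averaged across trials (trials in which the cell
#' never fires at any amplitude contribute nothing).
#'
#' @param rec a [cell_recording()].
#' @param detector a [spike_detector()].
#' @return Mean rheobase in pA, or `NA` (with attribute `nonfiring = TRUE`)
#'   when no trial fires at any amplitude.
#' @export
measure_rheobase <- function(rec, detector = spike_detector()) {
  p <- rec$protocol
  amps <- sort(p$amplitudes_pA[p$amplitudes_pA > 0])
  if (length(amps) == 0)
    sc_stop("protocol has no depolarizing amplitude", "stepclamp_protocol_error")
  per_trial <- rep(NA_real_, p$n_trials)
  for (trial in seq_len(p$n_trials)) {
    for (amp in amps) {
      sw <- Filter(function(s) s$amplitude_pA == amp && s$trial_index == trial,
                   rec$sweeps)
      if (length(sw) == 0) next
      if (nrow(sweep_spike_train(rec, sw[[1]], detector)) >= 1) {
        per_trial[trial] <- amp
        break
      }
    }
  }
  if (all(is.na(per_trial)))
    return(structure(NA_real_, nonfiring = TRUE))
  mean(per_trial, na.rm = TRUE)
}

# locate the cell's first AP at its minimal firing step:
# smallest per-trial rheobase amplitude, first trial firing there
first_spike_at_rheobase <- function(rec, detector = spike_detector()) {
  p <- rec$protocol
  amps <- sort(p$amplitudes_pA[p$amplitudes_pA > 0])
  for (amp in amps) {
    for (trial in seq_len(p$n_trials)) {
      sw <- Filter(function(s) s$amplitude_pA == amp && s$trial_index == trial,
                   rec$sweeps)
      if (length(sw) == 0) next
      tr <- sweep_spike_train(rec, sw[[1]], detector)
      if (nrow(tr) >= 1)
        return(list(sweep = sw[[1]], train = tr, amplitude_pA = amp,
                    trial = trial))
    }
  }
  NULL
}

#' Action-potential threshold of the first AP fired
#'
#' Threshold voltage of the first spike on the cell's minimal firing step,
#' both absolute and normalized to the resting membrane potential.
#'
#' @param rec a [cell_recording()].
#' @param rmp_mV resting potential; measured with [measure_rmp()] when not
#'   supplied.
#' @param detector a [spike_detector()].
#' @return List with `threshold_mV` and `threshold_rel_mV`
#'   (`threshold - RMP`); both `NA` for a non-firing cell.
#' @export
ap_threshold <- function(rec, rmp_mV = NULL, detector = spike_detector()) {
  fs <- first_spike_at_rheobase(rec, detector)
  if (is.null(fs))
    return(list(threshold_mV = NA_real_, threshold_rel_mV = NA_real_))
  if (is.null(rmp_mV)) rmp_mV <- measure_rmp(rec)$rmp_mV
  thr <- fs$train$threshold_mV[1]
  list(threshold_mV = thr, threshold_rel_mV = thr - rmp_mV)
}

# linear-interpolated crossing time of `level` between samples i and i+1
interp_cross <- function(t, v, i, level) {
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

# first crossing of `level` in direction `dir` (+1 rising, -1 falling)
# within index range [from, to); NA when absent
first_crossing <- function(t, v, from, to, level, dir) {
  idx <- seq(from, to - 1L)
  hit <- if (dir > 0) which(v[idx] < level & v[idx + 1L] >= level)
         else         which(v[idx] > level & v[idx + 1L] <= level)
  if (length(hit) == 0) return(NA_real_)
  interp_cross(t, v, idx[hit[1]], level)
}

#' Waveform morphometrics of the first AP at rheobase
#'
#' Measures the first action potential of the cell's minimal firing step:
#' amplitude (peak minus threshold), half-width (duration at 50% of
#' amplitude), 10-90% rise and 90-10% decay times between threshold and
#' peak levels, and the afterhyperpolarization (threshold minus the
#' post-spike minimum, positive when the trough is below threshold). All
#' level crossings are located by linear interpolation between samples; the
#' AHP trough is searched from the peak to the next spike's threshold or
#' `ahp_window_ms`, whichever comes first.
#'
#' @param rec a [cell_recording()].
#' @param detector a [spike_detector()].
#' @return List with `threshold_mV`, `amplitude_mV`, `halfwidth_ms`,
#'   `rise_ms`, `decay_ms`, `ahp_mV` (all `NA` for non-firing cells;
#'   `ahp_mV` alone `NA` when the window is empty).
#' @export
ap_waveform <- function(rec, detector = spike_detector()) {
  na <- list(threshold_mV = NA_real_, amplitude_mV = NA_real_,
             halfwidth_ms = NA_real_, rise_ms = NA_real_,
             decay_ms = NA_real_, ahp_mV = NA_real_)
  fs <- first_spike_at_rheobase(rec, detector)
  if (is.null(fs)) return(na)

  t <- fs$sweep$time_s
  v <- fs$sweep$voltage_mV
  sp <- fs$train[1, ]
  thr <- sp$threshold_mV
  pk <- sp$peak_mV
  amp <- pk - thr
  ip <- sp$peak_index
  it <- sp$threshold_index

  # falling-limb search end: next spike threshold or peak + ahp window
  dt <- t[2] - t[1]
  end <- min(length(v), ip + as.integer(round(detector$ahp_window_ms / 1000 / dt)))
  if (nrow(fs$train) >= 2)
    end <- min(end, fs$train$threshold_index[2])

  lev <- function(f) thr + f * amp
  r50 <- first_crossing(t, v, it, ip + 1L, lev(0.5), +1)
  f50 <- first_crossing(t, v, ip, end, lev(0.5), -1)
  r10 <- first_crossing(t, v, it, ip + 1L, lev(0.1), +1)
  r90 <- first_crossing(t, v, it, ip + 1L, lev(0.9), +1)
  f90 <- first_crossing(t, v, ip, end, lev(0.9), -1)
  f10 <- first_crossing(t, v, ip, end, lev(0.1), -1)

  ahp <- NA_real_
  if (end > ip + 1L) {
    trough <- min(v[(ip + 1L):end])
    ahp <- thr - trough
  }
  list(threshold_mV = thr, amplitude_mV = amp,
       halfwidth_ms = 1000 * (f50 - r50),
       rise_ms = 1000 * (r90 - r10),
       decay_ms = 1000 * (f10 - f90),
       ahp_mV = ahp)
}

#' Spike counts per depolarizing step (f-I table)
#'
#' @param rec a [cell_recording()].
#' @param detector a [spike_detector()].
#' @return Data frame `amplitude_pA`, `ap_count` (count averaged over
#'   trials) for every depolarizing amplitude.
#' @export
count_aps <- function(rec, detector = spike_detector()) {
  p <- rec$protocol
  amps <- sort(p$amplitudes_pA[p$amplitudes_pA > 0])
  counts <- vapply(amps, function(amp) {
    sw <- sweeps_at(rec, amp)
    mean(vapply(sw, function(s)
      nrow(sweep_spike_train(rec, s, detector)), numeric(1)))
  }, numeric(1))
  data.frame(amplitude_pA = amps, ap_count = counts)
}

#' Did the cell fire at a given step?
#'
#' Per-cell binary firing indicator at one amplitude (default the first
#' depolarizing step, +100 pA): 1 when at least one spike is detected in a
#' majority of trials (`rule = "majority"`, the default) or in any trial
#' (`rule = "any"`).
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA step amplitude.
#' @param rule trial-aggregation rule.
#' @param detector a [spike_detector()].
#' @return 0 or 1.
#' @export
cell_fired <- function(rec, amplitude_pA = 100, rule = c("majority", "any"),
                       detector = spike_detector()) {
  rule <- match.arg(rule)
  sw <- sweeps_at(rec, amplitude_pA)
  if (length(sw) == 0)
    sc_stop(sprintf("amplitude %g pA not in protocol", amplitude_pA),
            "stepclamp_protocol_error")
  fired <- vapply(sw, function(s)
    nrow(sweep_spike_train(rec, s, detector)) >= 1, logical(1))
  crit <- if (rule == "majority") sum(fired) > length(fired) / 2 else any(fired)
  as.integer(crit)
}

#' Group firing fraction
#'
#' Summarizes per-cell binary indicators (firing at a step, resting below a
#' voltage category, ...) as the `k/n` fraction the study reports.
#'
#' @param indicators vector of 0/1 per cell (`NA` dropped).
#' @return List with `k`, `n`, `fraction` and `percent`.
#' @export
fraction_summary <- function(indicators) {
  x <- indicators[!is.na(indicators)]
  k <- sum(x == 1)
  n <- length(x)
  list(k = k, n = n, fraction = k / n, percent = 100 * k / n)
}

#' Firing probability at a step across a cohort
#'
#' @param recordings list of [cell_recording()] objects.
#' @param amplitude_pA step amplitude (default +100 pA).
#' @param rule,detector passed to [cell_fired()].
#' @return List with per-cell `indicators` (named by cell) and the group
#'   [fraction_summary()].
#' @export
firing_probability <- function(recordings, amplitude_pA = 100,
                               rule = c("majority", "any"),
                               detector = spike_detector()) {
  rule <- match.arg(rule)
  ind <- vapply(recordings, cell_fired, numeric(1),
                amplitude_pA = amplitude_pA, rule = rule, detector = detector)
  names(ind) <- vapply(recordings, `[[`, character(1), "cell_id")
  list(indicators = ind, summary = fraction_summary(ind))
}

#' Delay from step onset to the first AP peak
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA step amplitude.
#' @param detector a [spike_detector()].
#' @return Delay in seconds, averaged over the trials that fired; `NA` when
#'   no trial fires at this amplitude.
#' @export
delay_to_first_spike <- function(rec, amplitude_pA,
                                 detector = spike_detector()) {
  sw <- sweeps_at(rec, amplitude_pA)
  if (length(sw) == 0)
    sc_stop(sprintf("amplitude %g pA not in protocol", amplitude_pA),
            "stepclamp_protocol_error")
  on <- rec$protocol$pre_step_s
  delays <- vapply(sw, function(s) {
    tr <- sweep_spike_train(rec, s, detector)
    if (nrow(tr) == 0) NA_real_ else tr$peak_time_s[1] - on
  }, numeric(1))
  if (all(is.na(delays))) NA_real_ else mean(delays, na.rm = TRUE)
}

#' Instantaneous firing frequencies of a spike train
#'
#' Frequency of each interspike interval, indexed by interval number:
#' `f_i = 1 / (t_{i+1} - t_i)` from spike peak times.
#'
#' @param peak_times_s spike peak times in seconds (a `spike_train` data
#'   frame is also accepted).
#' @return Numeric vector of frequencies in Hz (empty for < 2 spikes).
#' @export
instantaneous_frequencies <- function(peak_times_s) {
  if (is.data.frame(peak_times_s)) peak_times_s <- peak_times_s$peak_time_s
  if (length(peak_times_s) < 2) return(numeric(0))
  1 / diff(peak_times_s)
}

# per-interval frequencies at one amplitude, averaged across trials
# (each interval index averaged over the trials that reached it)
inst_freq_at <- function(rec, amplitude_pA, detector = spike_detector()) {
  sw <- sweeps_at(rec, amplitude_pA)
  per_trial <- lapply(sw, function(s)
    instantaneous_frequencies(sweep_spike_train(rec, s, detector)))
  nmax <- max(0L, vapply(per_trial, length, integer(1)))
  if (nmax == 0L) return(numeric(0))
  mat <- vapply(per_trial, function(f) c(f, rep(NA_real_, nmax - length(f))),
                numeric(nmax))
  rowMeans(matrix(mat, nrow = nmax), na.rm = TRUE)
}

#' Accommodation summary of an instantaneous-frequency profile
#'
#' Early behaviour is the first three interval frequencies verbatim; late
#' behaviour is the mean frequency over an inclusive interval-index range
#' (the study collapses intervals 15-20 at +200 pA and 19-25 at +300 pA).
#' A train too short to cover the late range yields `NA` — such cells are
#' excluded from the late-accommodation comparison.
#'
#' @param freqs instantaneous frequencies indexed by interval number.
#' @param late_range inclusive index range `c(first, last)`.
#' @return List with `f1`, `f2`, `f3` and `late_mean_Hz`.
#' @export
accommodation_summary <- function(freqs, late_range = c(15, 20)) {
  pick <- function(i) if (length(freqs) >= i) freqs[i] else NA_real_
  late <- if (length(freqs) >= late_range[2])
    mean(freqs[late_range[1]:late_range[2]])
  else NA_real_
  list(f1 = pick(1), f2 = pick(2), f3 = pick(3), late_mean_Hz = late)
}
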