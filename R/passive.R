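# window helpers: all steady-state measures use the final `window` of the
# stimulus epoch, all baselines the final 100 ms of the pre-step epoch
baseline_window <- function(protocol, window_s = 0.1) {
  c(protocol$pre_step_s - window_s, protocol$pre_step_s)
}
steady_window <- function(protocol, window_s = 0.16) {
  off <- protocol$pre_step_s + protocol$step_dur_s
  c(off - window_s, off)
}
window_mean <- function(time_s, voltage_mV, win) {
  sel <- time_s >= win[1] & time_s < win[2]
  mean(voltage_mV[sel])
}

# replace each detected spike (threshold point to the first post-peak
# return below threshold) with a straight line, per trial
clip_spikes <- function(voltage_mV, time_s, detector = spike_detector()) {
  tr <- detect_spikes(voltage_mV, time_s, detector)
  if (nrow(tr) == 0) return(list(voltage_mV = voltage_mV, clipped = logical(length(voltage_mV))))
  v <- voltage_mV
  clipped <- logical(length(v))
  for (k in seq_len(nrow(tr))) {
    i0 <- tr$threshold_index[k]
    ip <- tr$peak_index[k]
    thr <- tr$threshold_mV[k]
    i1 <- ip + 1L
    while (i1 < length(v) && v[i1] > thr &&
           (time_s[i1] - time_s[ip]) < 0.01) i1 <- i1 + 1L
    if (i1 - i0 >= 2L) {
      idx <- (i0 + 1L):(i1 - 1L)
      v[idx] <- v[i0] + (v[i1] - v[i0]) * (idx - i0) / (i1 - i0)
      clipped[idx] <- TRUE
    }
  }
  list(voltage_mV = v, clipped = clipped)
}

#' Resting membrane potential
#'
#' Mean voltage over the final 100 ms before step onset. By default the
#' baseline of the first recorded sweep set is used (the most
#' hyperpolarized amplitude, its trials averaged); `baseline = "all"`
#' averages every sweep's baseline instead. Also reports the binary
#' indicator for resting below -80 mV used in category tallies.
#'
#' @param rec a [cell_recording()].
#' @param baseline `"first"` (default) or `"all"`.
#' @param window_s baseline window length (the pre-step epoch must be at
#'   least this long).
#' @return List with `rmp_mV` and `rmp_below_neg80` (0/1).
#' @export
measure_rmp <- function(rec, baseline = c("first", "all"), window_s = 0.1) {
  baseline <- match.arg(baseline)
  p <- rec$protocol
  if (p$pre_step_s < window_s - 1e-12)
    sc_stop(sprintf("pre-step epoch (%g s) shorter than the %g s baseline window",
                    p$pre_step_s, window_s), "stepclamp_insufficient_baseline_error")
  win <- baseline_window(p, window_s)
  amps <- if (baseline == "first") min(p$amplitudes_pA) else p$amplitudes_pA
  vals <- unlist(lapply(amps, function(a)
    vapply(sweeps_at(rec, a), function(s)
      window_mean(s$time_s, s$voltage_mV, win), numeric(1))))
  rmp <- mean(vals)
  list(rmp_mV = rmp, rmp_below_neg80 = as.integer(rmp < -80))
}

#' Steady-state voltage response to a step
#'
#' Magnitude of the steady-state deflection `|steady - baseline|` at one
#' amplitude. Steady state is the mean over the final 160 ms of the
#' stimulus epoch; on depolarizing sweeps detected action potentials are
#' clipped (replaced threshold-to-threshold by linear interpolation) per
#' trial before the trials are averaged pointwise.
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA step amplitude (must be in the protocol).
#' @param detector a [spike_detector()] for spike clipping.
#' @param window_s steady-state window length.
#' @return Deflection magnitude in mV.
#' @export
measure_voltage_response <- function(rec, amplitude_pA,
                                     detector = spike_detector(),
                                     window_s = 0.16) {
  p <- rec$protocol
  sw <- sweeps_at(rec, amplitude_pA)
  if (length(sw) == 0)
    sc_stop(sprintf("amplitude %g pA not in protocol", amplitude_pA),
            "stepclamp_protocol_error")
  swin <- steady_window(p, window_s)
  bwin <- baseline_window(p, min(0.1, p$pre_step_s))
  n <- length(sw[[1]]$voltage_mV)
  vs <- matrix(NA_real_, n, length(sw))
  all_clipped <- rep(amplitude_pA > 0, n)
  for (i in seq_along(sw)) {
    if (amplitude_pA > 0) {
      cl <- clip_spikes(sw[[i]]$voltage_mV, sw[[i]]$time_s, detector)
      vs[, i] <- cl$voltage_mV
      all_clipped <- all_clipped & cl$clipped
    } else {
      vs[, i] <- sw[[i]]$voltage_mV
    }
  }
  t <- sw[[1]]$time_s
  in_steady <- t >= swin[1] & t < swin[2]
  if (any(in_steady) && all(all_clipped[in_steady]))
    sc_stop("entire steady-state window consumed by spikes",
            "stepclamp_undefined_response_error")
  avg <- rowMeans(vs)
  abs(window_mean(t, avg, swin) - window_mean(t, avg, bwin))
}

#' Input resistance at the -100 pA step
#'
#' `R_I = deflection(mV) / 100 pA * 1000` MOhm from the steady-state
#' deflection at the -100 pA hyperpolarizing step, where the
#' hyperpolarization-activated sag current is negligible.
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA measurement amplitude, -100 pA by definition.
#' @return Input resistance in MOhm (positive).
#' @export
measure_input_resistance <- function(rec, amplitude_pA = -100) {
  if (!(amplitude_pA %in% rec$protocol$amplitudes_pA))
    sc_stop(sprintf("protocol lacks the %g pA step required for input resistance",
                    amplitude_pA), "stepclamp_protocol_error")
  defl <- measure_voltage_response(rec, amplitude_pA)
  defl / abs(amplitude_pA) * 1000
}

#' Membrane time constant (67% rule)
#'
#' Time after step onset at which the trial-averaged voltage first reaches
#' 67% of its steady-state deflection, located by linear interpolation
#' between samples. Defined at hyperpolarizing steps; for an ideal RC
#' membrane this equals `tau * ln(1/0.33) = 1.109 tau`.
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA a hyperpolarizing (< 0) amplitude.
#' @param frac fraction of steady state defining the crossing.
#' @return Time to the crossing in ms.
#' @export
measure_time_constant <- function(rec, amplitude_pA, frac = 0.67) {
  if (amplitude_pA >= 0)
    sc_stop("time constant is defined at hyperpolarizing steps",
            "stepclamp_protocol_error")
  p <- rec$protocol
  avg <- average_trace(rec, amplitude_pA)
  t <- avg$time_s; v <- avg$voltage_mV
  base <- window_mean(t, v, baseline_window(p, min(0.1, p$pre_step_s)))
  steady <- window_mean(t, v, steady_window(p))
  target <- base + frac * (steady - base)
  on <- p$pre_step_s
  off <- on + p$step_dur_s
  from <- which(t >= on)[1]
  to <- max(which(t < off))
  tc <- first_crossing(t, v, from, to, target, if (steady < base) -1 else +1)
  if (is.na(tc))
    sc_stop(sprintf("voltage never reaches %g%% of steady state at %g pA",
                    100 * frac, amplitude_pA), "stepclamp_non_settling_error")
  1000 * (tc - on)
}

#' Voltage sag at the -400 pA step
#'
#' Sag is the difference between the steady-state voltage (mean of the
#' final 160 ms of the step) and the maximum negative peak during the step
#' on the trial-averaged trace — the current-clamp signature of the
#' hyperpolarization-activated (HCN/I_h) current. The normalized sag
#' divides it by the steady-state voltage response, making it comparable
#' across cells of different input resistance. A negative raw sag (peak
#' above steady state) is reported as-is with a QC flag, never clamped.
#'
#' @param rec a [cell_recording()].
#' @param amplitude_pA the sag amplitude, -400 pA by definition.
#' @return List with `sag_mV`, `response_mV`, `sag_norm` and `qc_anomaly`
#'   (TRUE when `sag_mV < 0`).
#' @export
measure_sag <- function(rec, amplitude_pA = -400) {
  p <- rec$protocol
  if (!(amplitude_pA %in% p$amplitudes_pA))
    sc_stop(sprintf("protocol lacks the %g pA step required for sag",
                    amplitude_pA), "stepclamp_protocol_error")
  avg <- average_trace(rec, amplitude_pA)
  t <- avg$time_s; v <- avg$voltage_mV
  on <- p$pre_step_s; off <- on + p$step_dur_s
  in_step <- t >= on & t < off
  steady <- window_mean(t, v, steady_window(p))
  peak <- min(v[in_step])
  sag <- steady - peak
  response <- measure_voltage_response(rec, amplitude_pA)
  if (response == 0)
    sc_stop("zero voltage response: normalized sag undefined",
            "stepclamp_undefined_normalization_error")
  list(sag_mV = sag, response_mV = response, sag_norm = sag / response,
       qc_anomaly = sag < 0)
}
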