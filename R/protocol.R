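#' Square-pulse step protocol
#'
#' Describes the command-current schedule of a current-clamp step experiment:
#' a series of square pulses of increasing amplitude, each preceded by a
#' baseline epoch and followed by a tail epoch, repeated for a fixed number of
#' trials per amplitude at a uniform sampling rate.
#'
#' The default instance is the dentate granule cell protocol used throughout
#' this package: 14 serial 100 pA steps from -400 to +900 pA, 800 ms step
#' duration, 3 trials per amplitude, sampled at 10 kHz. The baseline epoch
#' must be at least 100 ms because the resting-potential measurement is
#' defined on the final 100 ms before step onset.
#'
#' @param amplitudes_pA strictly increasing command amplitudes in pA.
#' @param pre_step_s baseline epoch duration in seconds (> 0).
#' @param step_dur_s stimulus epoch duration in seconds (> 0).
#' @param post_step_s tail epoch duration in seconds (> 0).
#' @param n_trials repeats per amplitude (>= 1).
#' @param sampling_rate_hz uniform sampling rate, at least 5000 Hz.
#'
#' @return An object of class `step_protocol`.
#' @export
#' @examples
#' p <- step_protocol()
#' length(p$amplitudes_pA)  # 14
step_protocol <- function(amplitudes_pA = seq(-400, 900, by = 100),
                          pre_step_s = 0.1,
                          step_dur_s = 0.8,
                          post_step_s = 0.2,
                          n_trials = 3,
                          sampling_rate_hz = 10000) {
  if (any(!is.finite(amplitudes_pA)) || is.unsorted(amplitudes_pA, strictly = TRUE))
    sc_stop("amplitudes_pA must be finite and strictly increasing",
            "stepclamp_protocol_error")
  for (d in c(pre_step_s = pre_step_s, step_dur_s = step_dur_s,
              post_step_s = post_step_s)) {
    if (!is.finite(d) || d <= 0)
      sc_stop("all epoch durations must be > 0", "stepclamp_protocol_error")
  }
  if (sampling_rate_hz < 5000)
    sc_stop("sampling_rate_hz must be >= 5000", "stepclamp_protocol_error")
  if (n_trials < 1)
    sc_stop("n_trials must be >= 1", "stepclamp_protocol_error")
  structure(list(
    amplitudes_pA = as.numeric(amplitudes_pA),
    pre_step_s = pre_step_s,
    step_dur_s = step_dur_s,
    post_step_s = post_step_s,
    n_trials = as.integer(n_trials),
    sampling_rate_hz = sampling_rate_hz
  ), class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> %d amplitudes (%g..%g pA), %g ms step, %d trials, %g kHz\n",
    length(x$amplitudes_pA), min(x$amplitudes_pA), max(x$amplitudes_pA),
    1000 * x$step_dur_s, x$n_trials, x$sampling_rate_hz / 1000))
  invisible(x)
}

# total sweep duration in seconds
protocol_duration_s <- function(protocol) {
  protocol$pre_step_s + protocol$step_dur_s + protocol$post_step_s
}

# number of samples per sweep (inclusive time grid 0..T)
protocol_n_samples <- function(protocol) {
  as.integer(round(protocol_duration_s(protocol) * protocol$sampling_rate_hz)) + 1L
}

# canonical time grid for one sweep
protocol_time_grid <- function(protocol) {
  n <- protocol_n_samples(protocol)
  (seq_len(n) - 1) / protocol$sampling_rate_hz
}

#' Single sweep container
#'
#' One recorded trace: the voltage response to one square current pulse.
#'
#' @param trial_index trial number, >= 1.
#' @param amplitude_pA command amplitude in pA.
#' @param time_s uniform time grid in seconds.
#' @param voltage_mV membrane voltage samples in mV (same length as `time_s`).
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(trial_index, amplitude_pA, time_s, voltage_mV) {
  if (length(time_s) != length(voltage_mV))
    sc_stop("time_s and voltage_mV must have equal length",
            "stepclamp_corruption_error")
  structure(list(
    trial_index = as.integer(trial_index),
    amplitude_pA = amplitude_pA,
    time_s = as.numeric(time_s),
    voltage_mV = as.numeric(voltage_mV)
  ), class = "sweep")
}

#' One cell's step-protocol recording
#'
#' Bundles every sweep recorded from one cell with its metadata. Sweeps are
#' stored in canonical order: ascending amplitude, then ascending trial.
#'
#' @param cell_id cell identifier.
#' @param group_label experimental group (e.g. `"Wt"`, `"Tg"`).
#' @param protocol a [step_protocol()].
#' @param sweeps list of [new_sweep()] objects.
#' @param rs_start_MOhm,rs_end_MOhm series resistance at trial start/end in
#'   MOhm; `NA` for synthetic cells where access resistance does not exist.
#' @param notes free-text metadata (drug cocktail, slice, ...).
#' @return An object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, group_label, protocol, sweeps,
                           rs_start_MOhm = NA_real_, rs_end_MOhm = NA_real_,
                           notes = "") {
  ord <- order(vapply(sweeps, `[[`, numeric(1), "amplitude_pA"),
               vapply(sweeps, `[[`, integer(1), "trial_index"))
  structure(list(
    cell_id = as.character(cell_id),
    group_label = as.character(group_label),
    rs_start_MOhm = rs_start_MOhm,
    rs_end_MOhm = rs_end_MOhm,
    notes = notes,
    protocol = protocol,
    sweeps = sweeps[ord]
  ), class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %s [%s], %d sweeps\n",
              x$cell_id, x$group_label, length(x$sweeps)))
  invisible(x)
}

# all sweeps of one amplitude, list of sweep objects
sweeps_at <- function(rec, amplitude_pA) {
  keep <- vapply(rec$sweeps, function(s) s$amplitude_pA == amplitude_pA,
                 logical(1))
  rec$sweeps[keep]
}

# pointwise trial-averaged trace at one amplitude -> list(time_s, voltage_mV)
average_trace <- function(rec, amplitude_pA) {
  sw <- sweeps_at(rec, amplitude_pA)
  if (length(sw) == 0)
    sc_stop(sprintf("no sweep at %g pA for cell %s", amplitude_pA, rec$cell_id),
            "stepclamp_protocol_error")
  v <- rowMeans(vapply(sw, `[[`, numeric(length(sw[[1]]$time_s)), "voltage_mV"))
  list(time_s = sw[[1]]$time_s, voltage_mV = v)
}

#' Validate a cell recording
#'
#' Checks the structural invariants of a [cell_recording()]: complete sweep
#' set (one sweep per amplitude x trial), equal-length time/voltage vectors,
#' uniform time grid at the protocol sampling rate, and positive series
#' resistance when recorded. Validation never raises; it reports.
#'
#' @param rec a [cell_recording()].
#' @param grid_tol_s tolerance on time-grid spacing in seconds.
#' @return A data frame of violations (zero rows when the recording is valid)
#'   with columns `rule`, `amplitude_pA`, `trial`, `message`.
#' @export
validate_recording <- function(rec, grid_tol_s = 1e-9) {
  out <- list()
  add <- function(rule, amp, trial, msg)
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, amplitude_pA = amp, trial = trial, message = msg,
      stringsAsFactors = FALSE)

  p <- rec$protocol
  want <- expand.grid(trial = seq_len(p$n_trials), amplitude_pA = p$amplitudes_pA)
  have <- data.frame(
    trial = vapply(rec$sweeps, `[[`, integer(1), "trial_index"),
    amplitude_pA = vapply(rec$sweeps, `[[`, numeric(1), "amplitude_pA"))
  key <- function(d) paste(d$amplitude_pA, d$trial)
  missing <- want[!(key(want) %in% key(have)), , drop = FALSE]
  if (nrow(missing) > 0)
    for (i in seq_len(nrow(missing)))
      add("partial sweep set", missing$amplitude_pA[i], missing$trial[i],
          "sweep missing from recording")

  dt <- 1 / p$sampling_rate_hz
  for (s in rec$sweeps) {
    if (length(s$time_s) != length(s$voltage_mV)) {
      add("length mismatch", s$amplitude_pA, s$trial_index,
          "time_s and voltage_mV differ in length")
      next
    }
    if (length(s$time_s) >= 2) {
      spacing <- diff(s$time_s)
      if (any(abs(spacing - dt) > grid_tol_s))
        add("grid spacing", s$amplitude_pA, s$trial_index,
            "non-uniform time grid or wrong sampling rate")
    }
    dur <- s$time_s[length(s$time_s)] - s$time_s[1]
    if (abs(dur - protocol_duration_s(p)) > dt)
      add("epoch coverage", s$amplitude_pA, s$trial_index,
          "sweep does not cover pre + step + post epochs")
  }

  for (f in c("rs_start_MOhm", "rs_end_MOhm")) {
    v <- rec[[f]]
    if (!is.na(v) && v <= 0)
      add("series resistance", NA_real_, NA_integer_,
          sprintf("%s must be > 0, got %g", f, v))
  }

  if (length(out) == 0)
    data.frame(rule = character(), amplitude_pA = numeric(),
               trial = integer(), message = character(),
               stringsAsFactors = FALSE)
  else
    do.call(rbind, out)
}

#' Adapter contract for external electrophysiology containers
#'
#' Generic that maps an external sweep container (for example an object read
#' from an ABF or NWB intracellular-ephys file by another package) to a
#' [cell_recording()]. The package provides a method for long-format data
#' frames with columns `trial`, `amplitude_pA`, `time_s`, `voltage_mV`;
#' adapters for binary acquisition formats can register further methods.
#'
#' @param x external object.
#' @param protocol the [step_protocol()] the data were acquired with.
#' @param cell_id,group_label metadata for the resulting recording.
#' @param ... passed to methods.
#' @return A [cell_recording()].
#' @export
as_cell_recording <- function(x, protocol, cell_id = "cell",
                              group_label = "unknown", ...) {
  UseMethod("as_cell_recording")
}

#' @rdname as_cell_recording
#' @export
as_cell_recording.data.frame <- function(x, protocol, cell_id = "cell",
                                         group_label = "unknown", ...) {
  need <- c("trial", "amplitude_pA", "time_s", "voltage_mV")
  if (!all(need %in% names(x)))
    sc_stop(paste("data frame adapter needs columns:",
                  paste(need, collapse = ", ")), "stepclamp_format_error")
  parts <- split(x, list(x$amplitude_pA, x$trial), drop = TRUE)
  sweeps <- lapply(parts, function(d)
    new_sweep(d$trial[1], d$amplitude_pA[1], d$time_s, d$voltage_mV))
  cell_recording(cell_id, group_label, protocol, unname(sweeps), ...)
}
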