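# syntactic column name for a signed amplitude: -400 -> neg400, 100 -> pos100
amp_col <- function(amplitude_pA)
  paste0(ifelse(amplitude_pA < 0, "neg", "pos"), abs(amplitude_pA))

#' Extract the full feature vector of one cell
#'
#' Runs the complete measurement battery on one recording: resting
#' potential, input resistance, per-amplitude membrane time constants and
#' voltage responses, sag, rheobase, AP threshold, first-AP waveform
#' morphometrics, firing indicator and delay at the first depolarizing
#' step, the f-I spike-count table, and early/late accommodation summaries
#' at +200 and +300 pA. Non-firing cells get `NA` in every spike-dependent
#' column while the passive columns remain defined; per-measure failures
#' are recorded as `NA` rather than aborting the cell.
#'
#' @param rec a [cell_recording()].
#' @param detector a [spike_detector()].
#' @param accom_ranges named list mapping amplitude column (e.g.
#'   `"pos200"`) to the inclusive late interval range.
#' @return A one-row data frame (the cohort feature-table schema).
#' @export
extract_features <- function(rec, detector = spike_detector(),
                             accom_ranges = list(pos200 = c(15, 20),
                                                 pos300 = c(19, 25))) {
  p <- rec$protocol
  rec <- cache_spikes(rec, detector)
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)

  row <- list(cell_id = rec$cell_id, group_label = rec$group_label,
              rs_start_MOhm = rec$rs_start_MOhm, rs_end_MOhm = rec$rs_end_MOhm)

  rmp <- safe(measure_rmp(rec))
  row$rmp_mV <- if (is.null(rmp)) NA_real_ else rmp$rmp_mV
  row$rmp_below_neg80 <- if (is.null(rmp)) NA_integer_ else rmp$rmp_below_neg80

  ri <- safe(measure_input_resistance(rec))
  row$r_in_MOhm <- ri %||% NA_real_

  for (amp in sort(p$amplitudes_pA[p$amplitudes_pA < 0])) {
    tc <- safe(measure_time_constant(rec, amp))
    row[[paste0("tau67_", amp_col(amp), "_ms")]] <- tc %||% NA_real_
  }

  for (amp in intersect(c(100, -400), p$amplitudes_pA)) {
    vr <- safe(measure_voltage_response(rec, amp, detector))
    row[[paste0("v_resp_", amp_col(amp), "_mV")]] <- vr %||% NA_real_
  }

  sag <- safe(measure_sag(rec))
  row$sag_mV <- if (is.null(sag)) NA_real_ else sag$sag_mV
  row$sag_norm <- if (is.null(sag)) NA_real_ else sag$sag_norm

  rheo <- measure_rheobase(rec, detector)
  row$rheobase_pA <- as.numeric(rheo)

  thr <- ap_threshold(rec, rmp_mV = row$rmp_mV, detector = detector)
  row$ap_threshold_mV <- thr$threshold_mV
  row$ap_threshold_rel_mV <- thr$threshold_rel_mV

  wf <- ap_waveform(rec, detector)
  row$ap_amp_mV <- wf$amplitude_mV
  row$ap_halfwidth_ms <- wf$halfwidth_ms
  row$ap_rise_ms <- wf$rise_ms
  row$ap_decay_ms <- wf$decay_ms
  row$ap_ahp_mV <- wf$ahp_mV

  min_dep <- min(p$amplitudes_pA[p$amplitudes_pA > 0])
  row$fired_pos100 <- safe(cell_fired(rec, min_dep, detector = detector)) %||%
    NA_integer_
  row$delay_pos100_s <- safe(delay_to_first_spike(rec, min_dep, detector)) %||%
    NA_real_

  fi <- count_aps(rec, detector)
  for (i in seq_len(nrow(fi)))
    row[[paste0("ap_count_", amp_col(fi$amplitude_pA[i]))]] <- fi$ap_count[i]

  for (col in names(accom_ranges)) {
    amp <- as.numeric(sub("pos", "", sub("neg", "-", col)))
    if (!(amp %in% p$amplitudes_pA)) next
    freqs <- inst_freq_at(rec, amp, detector)
    acc <- accommodation_summary(freqs, accom_ranges[[col]])
    row[[paste0("f1_", col, "_Hz")]] <- acc$f1
    row[[paste0("f2_", col, "_Hz")]] <- acc$f2
    row[[paste0("f3_", col, "_Hz")]] <- acc$f3
    row[[paste0("late_mean_", col, "_Hz")]] <- acc$late_mean_Hz
  }

  as.data.frame(row, stringsAsFactors = FALSE)
}
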