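#' Write recordings to a sweep bundle
#'
#' Serializes a collection of [cell_recording()] objects to a plain-text
#' bundle: a `manifest.json` holding the protocol and per-cell metadata, and
#' one long `sweeps.csv` with columns
#' `cell_id, trial, amplitude_pA, time_s, voltage_mV`. Voltages are written
#' with full double precision, so a write/read round trip reproduces every
#' sample to well under 1e-4 mV.
#'
#' @param recordings list of [cell_recording()] objects sharing one protocol.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_sweep_bundle <- function(recordings, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) sc_stop(sprintf("cannot create bundle directory '%s'", path),
                   "stepclamp_io_error")

  protocol <- if (length(recordings) > 0) recordings[[1]]$protocol else step_protocol()
  cells <- lapply(recordings, function(r) list(
    cell_id = r$cell_id,
    group_label = r$group_label,
    rs_start_MOhm = r$rs_start_MOhm,
    rs_end_MOhm = r$rs_end_MOhm,
    notes = r$notes
  ))
  manifest <- list(
    format_version = "1.0",
    protocol = unclass(protocol),
    cells = cells
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)

  tabs <- lapply(recordings, function(r)
    data.table::rbindlist(lapply(r$sweeps, function(s)
      data.table::data.table(
        cell_id = r$cell_id, trial = s$trial_index,
        amplitude_pA = s$amplitude_pA,
        time_s = s$time_s, voltage_mV = s$voltage_mV))))
  tab <- if (length(tabs) > 0) data.table::rbindlist(tabs)
    else data.table::data.table(cell_id = character(), trial = integer(),
                                amplitude_pA = numeric(), time_s = numeric(),
                                voltage_mV = numeric())
  data.table::fwrite(tab, file.path(path, "sweeps.csv"))
  invisible(path)
}

#' Read a sweep bundle
#'
#' Reads a bundle written by [write_sweep_bundle()]. Sample values are
#' preserved exactly as stored (no resampling); sweeps are returned in
#' canonical order (ascending amplitude, then ascending trial).
#'
#' @param path bundle directory.
#' @return A list of [cell_recording()] objects.
#' @export
read_sweep_bundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    sc_stop(sprintf("no manifest.json in '%s': not a sweep bundle", path),
            "stepclamp_format_error")
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (!identical(manifest$format_version, "1.0"))
    sc_stop(sprintf("unsupported bundle format_version '%s'",
                    manifest$format_version %||% "<missing>"),
            "stepclamp_unsupported_version_error")

  pr <- manifest$protocol
  protocol <- step_protocol(
    amplitudes_pA = pr$amplitudes_pA,
    pre_step_s = pr$pre_step_s, step_dur_s = pr$step_dur_s,
    post_step_s = pr$post_step_s, n_trials = pr$n_trials,
    sampling_rate_hz = pr$sampling_rate_hz)
  n_expect <- protocol_n_samples(protocol)

  spath <- file.path(path, "sweeps.csv")
  if (!file.exists(spath))
    sc_stop(sprintf("no sweeps.csv in '%s'", path), "stepclamp_format_error")
  tab <- data.table::fread(spath, colClasses = list(
    character = "cell_id", integer = "trial",
    numeric = c("amplitude_pA", "time_s", "voltage_mV")))

  lapply(manifest$cells, function(meta) {
    sub <- tab[tab$cell_id == meta$cell_id, ]
    parts <- split(sub, list(sub$amplitude_pA, sub$trial), drop = TRUE)
    sweeps <- lapply(parts, function(d) {
      if (nrow(d) != n_expect)
        sc_stop(sprintf(
          "corrupt sweep for cell %s (amplitude %g pA, trial %d): %d samples, expected %d",
          meta$cell_id, d$amplitude_pA[1], d$trial[1], nrow(d), n_expect),
          "stepclamp_corruption_error")
      new_sweep(d$trial[1], d$amplitude_pA[1], d$time_s, d$voltage_mV)
    })
    cell_recording(
      meta$cell_id, meta$group_label, protocol, unname(sweeps),
      rs_start_MOhm = meta$rs_start_MOhm %||% NA_real_,
      rs_end_MOhm = meta$rs_end_MOhm %||% NA_real_,
      notes = meta$notes %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
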