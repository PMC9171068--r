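#' Series-resistance stability filter
#'
#' A cell fails when the access (series) resistance drifted by 20% or more
#' between the start and the end of the trial — the standard whole-cell
#' stability criterion; the boundary is inclusive. Cells without recorded
#' series resistance (synthetic cells) pass with an `assessed = FALSE`
#' flag.
#'
#' @param rec a [cell_recording()] (or a list with `rs_start_MOhm`,
#'   `rs_end_MOhm`).
#' @param max_change maximal tolerated fractional change (default 0.20).
#' @return List with `pass`, `change_frac` and `assessed`.
#' @export
series_resistance_filter <- function(rec, max_change = 0.20) {
  rs0 <- rec$rs_start_MOhm
  rs1 <- rec$rs_end_MOhm
  if (is.na(rs0) || is.na(rs1))
    return(list(pass = TRUE, change_frac = NA_real_, assessed = FALSE))
  if (rs0 <= 0 || rs1 <= 0)
    sc_stop("series resistance must be > 0", "stepclamp_metadata_error")
  change <- abs(rs1 - rs0) / rs0
  list(pass = change < max_change, change_frac = change, assessed = TRUE)
}

#' Minimum-spike inclusion rules for accommodation analyses
#'
#' The study requires more than 5 spikes at +100 pA for a cell to enter the
#' accommodation dataset, and (for the late-interval analyses) 17+ spikes
#' at steps of +200 pA and above; both printed variants are encoded as the
#' default per-amplitude rule table and can be overridden.
#'
#' @return Data frame with columns `min_amplitude_pA`, `max_amplitude_pA`,
#'   `min_count` (inclusion requires `count >= min_count`).
#' @export
min_spike_rules <- function() {
  data.frame(
    min_amplitude_pA = c(100, 200),
    max_amplitude_pA = c(100, Inf),
    min_count = c(6, 18)
  )
}

#' Apply minimum-spike inclusion rules
#'
#' @param ap_count spike count at the step (may be a trial-averaged,
#'   fractional count).
#' @param amplitude_pA the step amplitude.
#' @param rules rule table, see [min_spike_rules()].
#' @return `TRUE` when the cell is included at this amplitude. Amplitudes
#'   not covered by any rule are included.
#' @export
min_spike_filter <- function(ap_count, amplitude_pA, rules = min_spike_rules()) {
  hit <- rules$min_amplitude_pA <= amplitude_pA &
         amplitude_pA <= rules$max_amplitude_pA
  if (!any(hit)) return(TRUE)
  all(ap_count >= rules$min_count[hit])
}

#' Two-sided single-iteration Grubbs outlier test
#'
#' Flags at most one observation: the point with the maximum studentized
#' deviation `G = max |x - mean| / sd`, when `G` exceeds the critical value
#' \deqn{G^* = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}}}
#' with `t` the upper `alpha/(2n)` quantile of the t distribution on
#' `n - 2` degrees of freedom. Single-iteration by design, so applying the
#' filter to its own output changes nothing.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha significance level.
#' @return Integer vector of flagged indices (length 0 or 1), with
#'   attributes `G` and `G_crit`. Zero-variance input flags nothing.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  x <- values
  n <- length(x)
  if (n < 3)
    sc_stop("Grubbs test needs at least 3 observations",
            "stepclamp_insufficient_n_error")
  s <- sd(x)
  if (s == 0 || !is.finite(s))
    return(structure(integer(0), G = 0, G_crit = NA_real_))
  dev <- abs(x - mean(x)) / s
  G <- max(dev)
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  G_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  idx <- if (G > G_crit) which.max(dev) else integer(0)
  structure(as.integer(idx), G = G, G_crit = G_crit)
}

#' Quality-control report for a cohort
#'
#' Applies the series-resistance filter per cell, the minimum-spike
#' inclusion rules per (cell, amplitude), and the Grubbs outlier screen per
#' measure within each group. Excluded cells and flagged outliers are
#' reported, never silently dropped.
#'
#' @param recordings list of [cell_recording()] objects.
#' @param features feature table from [run_extract()] /
#'   [extract_features()].
#' @param measures feature columns to screen for outliers (default: the
#'   main continuous measures present in `features`).
#' @param alpha Grubbs significance level.
#' @param rules minimum-spike rule table.
#' @return A list with `series_resistance` (per-cell data frame),
#'   `min_spike` (per cell x gated amplitude data frame) and `outliers`
#'   (per measure x group data frame of flagged cells with G and critical
#'   value).
#' @export
qc_report <- function(recordings, features,
                      measures = NULL, alpha = 0.05,
                      rules = min_spike_rules()) {
  rs <- do.call(rbind, lapply(recordings, function(r) {
    f <- series_resistance_filter(r)
    data.frame(cell_id = r$cell_id, pass = f$pass,
               change_frac = f$change_frac, assessed = f$assessed,
               stringsAsFactors = FALSE)
  }))

  gate_amps <- unique(rules$min_amplitude_pA[is.finite(rules$min_amplitude_pA)])
  ms <- list()
  for (amp in gate_amps) {
    col <- paste0("ap_count_pos", amp)
    if (!col %in% names(features)) next
    ms[[length(ms) + 1L]] <- data.frame(
      cell_id = features$cell_id, amplitude_pA = amp,
      ap_count = features[[col]],
      included = vapply(features[[col]], function(k)
        !is.na(k) && min_spike_filter(k, amp, rules), logical(1)),
      stringsAsFactors = FALSE)
  }
  min_spike <- if (length(ms) > 0) do.call(rbind, ms) else NULL

  if (is.null(measures)) {
    default <- c("rmp_mV", "r_in_MOhm", "rheobase_pA", "sag_mV", "sag_norm",
                 "ap_threshold_mV", "ap_amp_mV", "ap_halfwidth_ms")
    measures <- intersect(default, names(features))
  }
  outs <- list()
  for (m in measures) {
    for (g in unique(features$group_label)) {
      sel <- features$group_label == g & !is.na(features[[m]])
      x <- features[[m]][sel]
      if (length(x) < 3) next
      flag <- grubbs_outlier(x, alpha)
      if (length(flag) == 1)
        outs[[length(outs) + 1L]] <- data.frame(
          measure = m, group_label = g,
          cell_id = features$cell_id[sel][flag],
          value = x[flag],
          G = attr(flag, "G"), G_crit = attr(flag, "G_crit"),
          stringsAsFactors = FALSE)
    }
  }
  outliers <- if (length(outs) > 0) do.call(rbind, outs) else NULL
  list(series_resistance = rs, min_spike = min_spike, outliers = outliers)
}
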