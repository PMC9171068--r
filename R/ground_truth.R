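#' Closed-form ground truth for a parameter set
#'
#' Derives the true passive properties implied by a [neuron_params()] set:
#' passive-limit input resistance `Rin = 1000/gL` (MOhm), membrane time
#' constant `tau = C/gL` (ms), and the rheobase. For a pure EIF cell
#' (`a_nS = 0`, `gh_nS = 0`) the rheobase is analytic,
#' `gL (VT - EL - DeltaT)` pA — the maximum steady current the subthreshold
#' dynamics can absorb; otherwise it is found numerically by
#' [numeric_rheobase()].
#'
#' @param params a [neuron_params()].
#' @param step_dur_s step duration used for the numeric rheobase.
#' @param compute_rheobase set `FALSE` to skip the (simulation-based)
#'   numeric rheobase for non-analytic parameter sets.
#' @return A list with `Rin_MOhm`, `tau_ms`, `rheobase_pA`,
#'   `rheobase_analytic` and `has_sag`.
#' @export
analytic_ground_truth <- function(params, step_dur_s = 0.8,
                                  compute_rheobase = TRUE) {
  stopifnot(inherits(params, "neuron_params"))
  analytic <- params$a_nS == 0 && params$gh_nS == 0
  rheo <- if (analytic) {
    params$gL_nS * (params$VT_mV - params$EL_mV - params$DeltaT_mV)
  } else if (compute_rheobase) {
    numeric_rheobase(params, step_dur_s = step_dur_s)
  } else {
    NA_real_
  }
  list(
    Rin_MOhm = 1000 / params$gL_nS,
    tau_ms = params$C_pF / params$gL_nS,
    rheobase_pA = rheo,
    rheobase_analytic = analytic,
    has_sag = params$gh_nS > 0
  )
}

#' Numeric rheobase by bisection
#'
#' Finds the minimum constant current that elicits at least one spike within
#' `step_dur_s`, by bisection on noise-free simulations started from the
#' settled resting state (the same initial condition every protocol sweep
#' uses). Returns the midpoint of the final bracket of width `<= tol_pA`.
#'
#' @param params a [neuron_params()] (noise is forced off).
#' @param step_dur_s step duration in seconds.
#' @param tol_pA bracket tolerance in pA.
#' @param upper_pA upper search bound; no spike there raises an error.
#' @param dt_ms integration step.
#' @return Rheobase estimate in pA.
#' @export
numeric_rheobase <- function(params, step_dur_s = 0.8, tol_pA = 1,
                             upper_pA = 2000, dt_ms = 0.05) {
  stopifnot(inherits(params, "neuron_params"), tol_pA > 0)
  p <- unclass(params)
  p$noise_sigma_pA <- 0
  state0 <- adex_settle_cpp(p, dt_ms, 2000)
  step_ms <- 1000 * step_dur_s
  fires <- function(amp)
    adex_count_spikes_cpp(p, state0, amp, step_ms, dt_ms) >= 1L
  if (!fires(upper_pA))
    sc_stop(sprintf("no spike at the %g pA search bound: rheobase unbounded",
                    upper_pA), "stepclamp_unbounded_error")
  lo <- 0
  hi <- upper_pA
  if (fires(lo)) return(0)
  while (hi - lo > tol_pA) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
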