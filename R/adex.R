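#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Parameter set for the single-compartment model used by the synthetic
#' cohort generator: an adaptive exponential integrate-and-fire (AdEx)
#' neuron extended with a first-order hyperpolarization-activated (H-type)
#' conductance that produces voltage sag and rebound, plus optional
#' Ornstein-Uhlenbeck current noise. The membrane equation is
#'
#' \deqn{C \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'       - g_h h (V - E_h) - w + I(t) + \xi(t)}
#'
#' with adaptation \eqn{\tau_w \dot w = a (V - E_L) - w} and sag activation
#' \eqn{\tau_h \dot h = h_\infty(V) - h},
#' \eqn{h_\infty(V) = 1/(1 + e^{(V - V_h)/k_h})}. When `V` reaches
#' `Vcut_mV` a spike is emitted (the output trace carries a stylized
#' one-sample excursion to `Vcut_mV`), `V` is reset to `Vreset_mV`, `w` is
#' incremented by `b_pA`, and the voltage is clamped for `tref_ms`.
#'
#' Units are mV, ms, pA, nS and pF throughout, so that nS x mV = pA and
#' pF/nS = ms exactly.
#'
#' @param C_pF membrane capacitance.
#' @param gL_nS leak conductance.
#' @param EL_mV leak reversal potential.
#' @param VT_mV exponential spike-initiation threshold.
#' @param DeltaT_mV spike-initiation slope factor; 0 disables the
#'   exponential term (pure leaky integrator).
#' @param Vreset_mV post-spike reset potential.
#' @param Vcut_mV numeric spike cutoff.
#' @param tref_ms absolute refractory period.
#' @param a_nS subthreshold adaptation coupling.
#' @param b_pA spike-triggered adaptation increment.
#' @param tauw_ms adaptation time constant.
#' @param gh_nS maximal sag (H-type) conductance; 0 disables sag.
#' @param Eh_mV sag reversal potential (mixed cation, ca. -30 mV).
#' @param Vh_mV,kh_mV sag activation midpoint and slope.
#' @param tauh_ms sag activation time constant.
#' @param noise_sigma_pA,noise_tau_ms Ornstein-Uhlenbeck current-noise
#'   standard deviation and correlation time; sigma 0 disables noise.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C_pF = 200, gL_nS = 10, EL_mV = -80,
                          VT_mV = -50, DeltaT_mV = 2,
                          Vreset_mV = -65, Vcut_mV = 0, tref_ms = 2,
                          a_nS = 0, b_pA = 0, tauw_ms = 250,
                          gh_nS = 0, Eh_mV = -30, Vh_mV = -108, kh_mV = 5,
                          tauh_ms = 50,
                          noise_sigma_pA = 0, noise_tau_ms = 5) {
  p <- list(C_pF = C_pF, gL_nS = gL_nS, EL_mV = EL_mV, VT_mV = VT_mV,
            DeltaT_mV = DeltaT_mV, Vreset_mV = Vreset_mV, Vcut_mV = Vcut_mV,
            tref_ms = tref_ms, a_nS = a_nS, b_pA = b_pA, tauw_ms = tauw_ms,
            gh_nS = gh_nS, Eh_mV = Eh_mV, Vh_mV = Vh_mV, kh_mV = kh_mV,
            tauh_ms = tauh_ms, noise_sigma_pA = noise_sigma_pA,
            noise_tau_ms = noise_tau_ms)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    sc_stop("all neuron parameters must be finite scalars",
            "stepclamp_validation_error")
  if (C_pF <= 0 || gL_nS < 0 || DeltaT_mV < 0 || tauw_ms <= 0 ||
      tauh_ms <= 0 || kh_mV <= 0 || noise_sigma_pA < 0 || noise_tau_ms <= 0 ||
      gh_nS < 0 || tref_ms < 0)
    sc_stop("parameter out of range (see ?neuron_params invariants)",
            "stepclamp_validation_error")
  if (!(Vreset_mV < VT_mV && VT_mV < Vcut_mV))
    sc_stop("need Vreset_mV < VT_mV < Vcut_mV", "stepclamp_validation_error")
  structure(p, class = "neuron_params")
}

# derive a per-sweep RNG seed below 2^31 from (seed, cell, amplitude, trial)
derive_seed <- function(seed, cell_index, amp_index, trial) {
  m <- 2147483629
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(cell_index) * 1000003) %% m
  s <- (s * 48271 + as.numeric(amp_index) * 10007 + as.numeric(trial)) %% m
  as.integer(s)
}

#' Simulate one cell under a step protocol
#'
#' Integrates the AdEx + sag model (see [neuron_params()]) through every
#' (amplitude, trial) sweep of a [step_protocol()]. The initial state of
#' every sweep is the stable resting state found by settling the model for
#' 2 s at zero current, mirroring the inter-sweep rest period of the
#' experimental protocol. Integration runs at a fine internal time step
#' (default 0.05 ms) and is resampled to the protocol sampling rate on
#' output. Deterministic given `(params, protocol, seed)`; with noise
#' disabled the trials of an amplitude are identical by construction.
#'
#' @param params a [neuron_params()].
#' @param protocol a [step_protocol()].
#' @param seed integer seed; per-sweep noise streams are derived from
#'   `(seed, cell_index, amplitude index, trial)` so any single sweep can be
#'   reproduced in isolation.
#' @param cell_id,group_label,cell_index metadata for the resulting
#'   recording.
#' @param dt_ms internal integration step (<= 0.05 ms; coerced to divide the
#'   output sample interval evenly).
#' @return A [cell_recording()] whose `spike_log` attribute is a data frame
#'   of simulator-emitted spike times (`amplitude_pA`, `trial`,
#'   `spike_time_s`), usable as an event-log oracle for spike detection.
#' @export
simulate_cell <- function(params, protocol = step_protocol(), seed = 1L,
                          cell_id = "cell_1", group_label = "sim",
                          cell_index = 1L, dt_ms = 0.05) {
  stopifnot(inherits(params, "neuron_params"), inherits(protocol, "step_protocol"))
  out_dt_ms <- 1000 / protocol$sampling_rate_hz
  out_every <- max(1L, as.integer(ceiling(out_dt_ms / dt_ms - 1e-9)))
  dt <- out_dt_ms / out_every
  if (dt > 0.05 + 1e-12)
    sc_stop("internal dt must be <= 0.05 ms", "stepclamp_validation_error")

  state0 <- adex_settle_cpp(unclass(params), dt, 2000)
  pre_ms <- 1000 * protocol$pre_step_s
  step_ms <- 1000 * protocol$step_dur_s
  post_ms <- 1000 * protocol$post_step_s
  tgrid <- protocol_time_grid(protocol)
  noisy <- params$noise_sigma_pA > 0

  sweeps <- vector("list", length(protocol$amplitudes_pA) * protocol$n_trials)
  log <- list()
  k <- 0L
  for (ai in seq_along(protocol$amplitudes_pA)) {
    amp <- protocol$amplitudes_pA[ai]
    first <- NULL
    for (trial in seq_len(protocol$n_trials)) {
      if (noisy || trial == 1L) {
        if (noisy) set.seed(derive_seed(seed, cell_index, ai, trial))
        res <- tryCatch(
          adex_sweep_cpp(unclass(params), state0, amp, pre_ms, step_ms,
                         post_ms, dt, out_every,
                         params$noise_sigma_pA, params$noise_tau_ms),
          error = function(e) sc_stop(
            sprintf("integration unstable for cell %s at %g pA, trial %d: %s",
                    cell_id, amp, trial, conditionMessage(e)),
            "stepclamp_instability_error"))
        if (trial == 1L) first <- res
      } else {
        res <- first  # noise-free trials are identical
      }
      k <- k + 1L
      sweeps[[k]] <- new_sweep(trial, amp, tgrid, res$voltage_mV)
      if (length(res$spike_times_ms) > 0)
        log[[length(log) + 1L]] <- data.frame(
          amplitude_pA = amp, trial = trial,
          spike_time_s = res$spike_times_ms / 1000)
    }
  }

  rec <- cell_recording(cell_id, group_label, protocol, sweeps)
  attr(rec, "spike_log") <- if (length(log) > 0) do.call(rbind, log)
    else data.frame(amplitude_pA = numeric(), trial = integer(),
                    spike_time_s = numeric())
  rec
}

#' Simulator spike event log
#'
#' @param rec a recording produced by [simulate_cell()].
#' @return Data frame of simulator-emitted spikes (`amplitude_pA`, `trial`,
#'   `spike_time_s`), or `NULL` for recordings without a log.
#' @export
spike_log <- function(rec) attr(rec, "spike_log")
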