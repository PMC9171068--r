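#' Truncated-normal parameter distribution
#'
#' One entry of a cohort regime: cell-to-cell variability of a single
#' neuron parameter, drawn from a normal distribution truncated to
#' `[lower, upper]` (sampled by inverse-CDF, so one uniform draw per value).
#' `sd = 0` pins the parameter at `mean`.
#'
#' @param mean,sd distribution mean and standard deviation.
#' @param lower,upper truncation bounds.
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(mean, sd = 0, lower = -Inf, upper = Inf) {
  if (sd < 0 || lower >= upper)
    sc_stop("need sd >= 0 and lower < upper", "stepclamp_spec_error")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "param_dist")
}

sample_param <- function(d) {
  if (d$sd == 0) return(d$mean)
  plo <- pnorm(d$lower, d$mean, d$sd)
  phi <- pnorm(d$upper, d$mean, d$sd)
  if (phi - plo < 1e-12)
    sc_stop("unsatisfiable truncation in parameter distribution",
            "stepclamp_spec_error")
  qnorm(runif(1, plo, phi), d$mean, d$sd)
}

#' Default group regimes for the synthetic cohort
#'
#' Parameter regimes emulating the two genotypes of the dentate granule
#' cell study the package was validated against. Both are ordinary granule
#' cell-like AdEx cells; they differ where the study reported differences:
#'
#' * `wt_like_regime()`: extracted input resistance centred near 134 MOhm,
#'   prominent sag conductance, moderate spike-triggered adaptation.
#' * `tg_like_regime()`: higher input resistance (centred near 168 MOhm,
#'   i.e. lower effective leak), 2-3 mV depolarized resting level, roughly
#'   halved sag conductance (reduced normalized sag), and a larger
#'   adaptation increment (greater spike-frequency accommodation).
#'
#' Note that with subthreshold adaptation coupling `a` the steady-state
#' input conductance is `gL + a`, so the leak means are chosen so that the
#' *extracted* input resistance, not `1000/gL`, lands on the target medians.
#'
#' @return A named list of [param_dist()] objects covering every
#'   [neuron_params()] field.
#' @export
wt_like_regime <- function() {
  list(
    C_pF = param_dist(200, 20, 140, 260),
    gL_nS = param_dist(6.2, 0.85, 4.2, 9.0),
    EL_mV = param_dist(-79, 2.5, -86, -72),
    VT_mV = param_dist(-61.5, 1.5, -65, -57),
    DeltaT_mV = param_dist(2),
    Vreset_mV = param_dist(-67.5),
    Vcut_mV = param_dist(0),
    tref_ms = param_dist(2),
    a_nS = param_dist(1.0, 0.25, 0.3, 1.8),
    b_pA = param_dist(11, 3, 4, 20),
    tauw_ms = param_dist(250, 40, 140, 360),
    gh_nS = param_dist(2.0, 0.5, 0.7, 3.6),
    Eh_mV = param_dist(-30),
    Vh_mV = param_dist(-108),
    kh_mV = param_dist(5),
    tauh_ms = param_dist(50),
    noise_sigma_pA = param_dist(0),
    noise_tau_ms = param_dist(5)
  )
}

#' @rdname wt_like_regime
#' @export
tg_like_regime <- function() {
  r <- wt_like_regime()
  r$gL_nS <- param_dist(4.9, 0.7, 3.2, 7.2)    # higher input resistance
  r$EL_mV <- param_dist(-76.5, 2.5, -83.5, -69.5)  # slightly depolarized
  r$gh_nS <- param_dist(1.0, 0.4, 0.2, 2.2)    # reduced sag
  r$b_pA  <- param_dist(22, 5, 10, 38)         # stronger accommodation
  r
}

#' Cohort specification
#'
#' Describes a synthetic two-group (or k-group) experiment: per-group
#' parameter regimes, cells per group, the step protocol, and a seed that
#' makes the whole cohort — parameter draws and simulations — fully
#' deterministic.
#'
#' @param groups named list mapping group label to a regime (named list of
#'   [param_dist()]); defaults to the two study-like regimes.
#' @param n_cells cells per group; scalar or vector named by group.
#' @param seed integer RNG seed.
#' @param protocol a [step_protocol()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list("Wt-like" = wt_like_regime(),
                                      "Tg-like" = tg_like_regime()),
                        n_cells = 20, seed = 42,
                        protocol = step_protocol()) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    sc_stop("groups must be a named list of regimes", "stepclamp_spec_error")
  if (length(n_cells) == 1) {
    n_cells <- rep(as.integer(n_cells), length(groups))
    names(n_cells) <- names(groups)
  }
  if (any(n_cells < 1))
    sc_stop("n_cells must be >= 1", "stepclamp_spec_error")
  structure(list(groups = groups, n_cells = n_cells,
                 seed = as.integer(seed), protocol = protocol),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Samples a [neuron_params()] set per cell from its group regime, derives
#' the cell's ground truth ([analytic_ground_truth()]), and simulates the
#' full step protocol ([simulate_cell()]). Fully deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param compute_rheobase compute the (simulation-based) numeric rheobase
#'   for each cell's ground-truth row; disable to save time when true
#'   rheobase is not needed.
#' @return A list with `recordings` (list of [cell_recording()]) and
#'   `ground_truth` (data frame: cell_id, group_label, every parameter, and
#'   the derived Rin_MOhm / tau_ms / rheobase_pA).
#' @export
generate_cohort <- function(spec, compute_rheobase = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  recordings <- list()
  gt <- list()
  cell_index <- 0L
  for (g in names(spec$groups)) {
    regime <- spec$groups[[g]]
    for (i in seq_len(spec$n_cells[[g]])) {
      cell_index <- cell_index + 1L
      draws <- lapply(regime, sample_param)
      params <- do.call(neuron_params, draws)
      cell_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), i)
      rec <- simulate_cell(params, spec$protocol, seed = spec$seed,
                           cell_id = cell_id, group_label = g,
                           cell_index = cell_index)
      truth <- analytic_ground_truth(params,
                                     step_dur_s = spec$protocol$step_dur_s,
                                     compute_rheobase = compute_rheobase)
      gt[[cell_index]] <- data.frame(
        cell_id = cell_id, group_label = g,
        as.data.frame(unclass(params)),
        Rin_MOhm = truth$Rin_MOhm, tau_ms = truth$tau_ms,
        rheobase_pA = truth$rheobase_pA,
        stringsAsFactors = FALSE)
      recordings[[cell_index]] <- rec
    }
  }
  list(recordings = recordings, ground_truth = do.call(rbind, gt))
}
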