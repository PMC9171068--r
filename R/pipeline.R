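#' Pipeline configuration
#'
#' One configuration object drives the full simulate - extract - QC -
#' compare pipeline. Exactly one of `cohort` (a [cohort_spec()]) or
#' `bundle` (path to a sweep bundle on disk) must be set; a seed is
#' required whenever a cohort is simulated.
#'
#' @param cohort a [cohort_spec()], or `NULL` when reading a bundle.
#' @param bundle path to a sweep bundle, or `NULL` when simulating.
#' @param detector a [spike_detector()].
#' @param qc_rules minimum-spike rule table ([min_spike_rules()]).
#' @param stats_policy test-selection policy for [compare_groups()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed integer seed (required with `cohort`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, bundle = NULL,
                            detector = spike_detector(),
                            qc_rules = min_spike_rules(),
                            stats_policy = "shapiro_gate",
                            out_dir = NULL, seed = NULL) {
  if (is.null(cohort) == is.null(bundle))
    sc_stop("exactly one of cohort spec or input bundle must be set",
            "stepclamp_config_error")
  if (!is.null(cohort) && is.null(seed))
    sc_stop("a seed is required when simulating a cohort",
            "stepclamp_config_error")
  if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
  }
  structure(list(cohort = cohort, bundle = bundle, detector = detector,
                 qc_rules = qc_rules, stats_policy = stats_policy,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Minimal file-driven front end to [pipeline_config()]: the file may set
#' `seed`, `n_cells`, `out_dir`, `bundle`, `stats_policy` and any
#' [spike_detector()] field under `detector:`; a missing `bundle` entry
#' means "simulate the default two-regime cohort".
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(spike_detector, cfg$detector %||% list())
  if (!is.null(cfg$bundle)) {
    pipeline_config(bundle = cfg$bundle, detector = det,
                    stats_policy = cfg$stats_policy %||% "shapiro_gate",
                    out_dir = cfg$out_dir)
  } else {
    spec <- cohort_spec(n_cells = cfg$n_cells %||% 20,
                        seed = cfg$seed %||% 1)
    pipeline_config(cohort = spec, detector = det,
                    stats_policy = cfg$stats_policy %||% "shapiro_gate",
                    out_dir = cfg$out_dir, seed = cfg$seed %||% 1)
  }
}

#' Simulate the configured cohort
#'
#' Delegates to [generate_cohort()]; when `out_dir` is set, writes the
#' sweep bundle and `ground_truth.csv` there.
#'
#' @param config a [pipeline_config()] with a cohort spec.
#' @param compute_rheobase forwarded to [generate_cohort()].
#' @return List with `recordings`, `ground_truth`, and `bundle_path`
#'   (`NULL` when nothing was written).
#' @export
run_simulate <- function(config, compute_rheobase = TRUE) {
  if (is.null(config$cohort))
    sc_stop("config has no cohort spec", "stepclamp_config_error")
  cohort <- generate_cohort(config$cohort, compute_rheobase = compute_rheobase)
  bundle_path <- NULL
  if (!is.null(config$out_dir)) {
    bundle_path <- file.path(config$out_dir, "bundle")
    write_sweep_bundle(cohort$recordings, bundle_path)
    data.table::fwrite(cohort$ground_truth,
                       file.path(config$out_dir, "ground_truth.csv"))
  }
  c(cohort, list(bundle_path = bundle_path))
}

#' Extract the feature table of a cohort
#'
#' One feature row per cell ([extract_features()]) plus the QC report
#' ([qc_report()]). Cells whose extraction fails in one measure get `NA`
#' there, never aborting the cohort; no cell is dropped (`nrow(features)`
#' equals the number of recordings).
#'
#' @param x list of [cell_recording()] objects, or a bundle path.
#' @param detector a [spike_detector()].
#' @param qc_rules minimum-spike rule table.
#' @param out_dir when set, writes `features.csv` and `qc_report.json`.
#' @return List with `features` (data frame) and `qc` (list).
#' @export
run_extract <- function(x, detector = spike_detector(),
                        qc_rules = min_spike_rules(), out_dir = NULL) {
  recordings <- if (is.character(x)) read_sweep_bundle(x) else x
  features <- do.call(rbind, lapply(recordings, extract_features,
                                    detector = detector))
  qc <- qc_report(recordings, features, rules = qc_rules)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(features, file.path(out_dir, "features.csv"))
    jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  list(features = features, qc = qc)
}

#' Compare the two groups on every measure
#'
#' Delegates to [compare_groups()]; when `out_dir` is set, writes
#' `stats.json` (per-measure test results plus descriptive k/n fractions
#' for the binary measures).
#'
#' @param features feature table.
#' @param policy test-selection policy.
#' @param out_dir optional output directory.
#' @param ... forwarded to [compare_groups()].
#' @return The [compare_groups()] result.
#' @export
run_compare <- function(features, policy = "shapiro_gate", out_dir = NULL,
                        ...) {
  res <- compare_groups(features, policy = policy, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  res
}

#' Run the full pipeline
#'
#' simulate (or load) - extract - QC - compare, deterministically per
#' `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @param compute_rheobase forwarded to [run_simulate()].
#' @return List with `recordings`, `ground_truth` (simulated runs only),
#'   `features`, `qc` and `stats`.
#' @export
run_pipeline <- function(config, compute_rheobase = FALSE) {
  if (!is.null(config$cohort)) {
    sim <- run_simulate(config, compute_rheobase = compute_rheobase)
    recordings <- sim$recordings
    ground_truth <- sim$ground_truth
  } else {
    recordings <- read_sweep_bundle(config$bundle)
    ground_truth <- NULL
  }
  ex <- run_extract(recordings, detector = config$detector,
                    qc_rules = config$qc_rules, out_dir = config$out_dir)
  stats <- run_compare(ex$features, policy = config$stats_policy,
                       out_dir = config$out_dir)
  list(recordings = recordings, ground_truth = ground_truth,
       features = ex$features, qc = ex$qc, stats = stats)
}
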