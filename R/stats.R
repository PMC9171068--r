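#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with Welch-Satterthwaite degrees of freedom,
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)`.
#'
#' @param x,y numeric samples (each `n >= 2`).
#' @return List with `t`, `df` (fractional) and `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    sc_stop("Welch t-test needs n >= 2 per group", "stepclamp_design_error")
  if (sd(x) == 0 && sd(y) == 0)
    sc_stop("both groups have zero variance", "stepclamp_degenerate_data_error")
  res <- t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test reported as `U = min(U_x, U_y)` with midrank ties. The
#' p-value is exact by enumeration when `n_x + n_y <= 20` and the pooled
#' data are tie-free, otherwise the normal approximation with tie and
#' continuity corrections is used; two-sided throughout.
#'
#' @param x,y numeric samples (each `n >= 1`).
#' @return List with `U`, `p` and `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    sc_stop("Mann-Whitney needs n >= 1 per group", "stepclamp_design_error")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  Ux <- unname(res$statistic)           # rank-sum U of x over y
  Uy <- length(x) * length(y) - Ux
  list(U = min(Ux, Uy), p = res$p.value, exact = use_exact)
}

#' Choose the two-group test for a measure
#'
#' Policies:
#' * `"shapiro_gate"` (default): Mann-Whitney when either group rejects
#'   normality by a Shapiro-Wilk test at `alpha`, Welch t otherwise (groups
#'   too small or too degenerate to test are treated as normal).
#' * `"force_welch"`, `"force_mwu"`: fixed choice.
#' * `"per_measure_map"`: look `measure` up in `map` (falling back to
#'   Welch), mirroring the study's implicit per-measure assignment
#'   (Mann-Whitney for input resistance and delay-to-first-AP, Welch t
#'   elsewhere).
#'
#' @param x,y the two samples.
#' @param policy selection policy.
#' @param measure measure name (used by `per_measure_map`).
#' @param map named character vector measure -> `"welch_t"` /
#'   `"mann_whitney_u"`.
#' @param alpha Shapiro-Wilk gate level.
#' @return `"welch_t"` or `"mann_whitney_u"`.
#' @export
choose_test <- function(x, y,
                        policy = c("shapiro_gate", "force_welch",
                                   "force_mwu", "per_measure_map"),
                        measure = NULL,
                        map = c(r_in_MOhm = "mann_whitney_u",
                                delay_pos100_s = "mann_whitney_u"),
                        alpha = 0.05) {
  policy <- match.arg(policy)
  switch(policy,
    force_welch = "welch_t",
    force_mwu = "mann_whitney_u",
    per_measure_map = {
      if (!is.null(measure) && measure %in% names(map)) unname(map[measure])
      else "welch_t"
    },
    shapiro_gate = {
      nonnormal <- function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 3 || length(unique(v)) < 3) return(FALSE)
        shapiro.test(v)$p.value < alpha
      }
      if (nonnormal(x) || nonnormal(y)) "mann_whitney_u" else "welch_t"
    })
}

sem <- function(v) sd(v) / sqrt(length(v))

#' Compare every measure between two groups
#'
#' Runs one two-group comparison per measure column of a feature table:
#' missing values are dropped pairwise, the test is selected by
#' [choose_test()], and per-group descriptives (n, mean, SEM, median) are
#' reported alongside the statistic. Binary 0/1 columns are summarized
#' descriptively as `k/n` fractions instead of being tested. No
#' multiple-comparison correction is applied by default, matching
#' per-measure reporting practice; `p_adjust = "holm"` adds an adjusted
#' column.
#'
#' @param features feature table with one row per cell (see
#'   [extract_features()]).
#' @param group_col name of the group-label column.
#' @param measures measure columns to compare; default: every numeric
#'   non-binary column except identifiers.
#' @param policy,map,alpha passed to [choose_test()].
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return List with `tests` (data frame, one row per measure: test,
#'   statistic, df, p, per-group descriptives) and `fractions` (data frame
#'   of binary measures as k/n and percent per group).
#' @export
compare_groups <- function(features, group_col = "group_label",
                           measures = NULL,
                           policy = "shapiro_gate",
                           map = c(r_in_MOhm = "mann_whitney_u",
                                   delay_pos100_s = "mann_whitney_u"),
                           alpha = 0.05, p_adjust = "none") {
  if (!group_col %in% names(features))
    sc_stop(sprintf("missing group column '%s'", group_col),
            "stepclamp_design_error")
  groups <- unique(features[[group_col]])
  if (length(groups) != 2)
    sc_stop("compare_groups needs exactly two groups", "stepclamp_design_error")
  if (any(table(features[[group_col]]) < 2))
    sc_stop("each group needs at least 2 cells", "stepclamp_design_error")

  is_binary <- function(v) is.numeric(v) && any(!is.na(v)) &&
    all(v[!is.na(v)] %in% c(0, 1))
  num_cols <- names(features)[vapply(features, function(v)
    is.numeric(v) && any(!is.na(v)), logical(1))]
  num_cols <- setdiff(num_cols, group_col)
  bin_cols <- num_cols[vapply(features[num_cols], is_binary, logical(1))]
  if (is.null(measures)) measures <- setdiff(num_cols, bin_cols)

  rows <- lapply(measures, function(m) {
    x <- features[[m]][features[[group_col]] == groups[1]]
    y <- features[[m]][features[[group_col]] == groups[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out <- data.frame(
      measure = m, test = NA_character_, statistic = NA_real_,
      df = NA_real_, p = NA_real_,
      n1 = length(x), mean1 = mean(x), sem1 = sem(x), median1 = median(x),
      n2 = length(y), mean2 = mean(y), sem2 = sem(y), median2 = median(y),
      stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) return(out)
    if (sd(x) == 0 && sd(y) == 0) return(out)
    test <- choose_test(x, y, policy = policy, measure = m, map = map,
                        alpha = alpha)
    res <- if (test == "welch_t") welch_t(x, y) else mann_whitney_u(x, y)
    out$test <- test
    out$statistic <- if (test == "welch_t") res$t else res$U
    out$df <- if (test == "welch_t") res$df else NA_real_
    out$p <- res$p
    out
  })
  tests <- do.call(rbind, rows)
  if (p_adjust != "none") tests$p_adj <- p.adjust(tests$p, method = p_adjust)
  attr(tests, "groups") <- groups

  fracs <- lapply(bin_cols, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      s <- fraction_summary(features[[m]][features[[group_col]] == g])
      data.frame(measure = m, group = g, k = s$k, n = s$n,
                 fraction = s$fraction, percent = s$percent,
                 stringsAsFactors = FALSE)
    }))
  })
  fractions <- if (length(fracs) > 0) do.call(rbind, fracs) else NULL

  list(tests = tests, fractions = fractions)
}
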