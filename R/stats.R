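#' Age-regression pretest for one group
#'
#' Ordinary least-squares regression of a thickness metric on age within
#' one group, reporting the slope (um/week, sign retained: negative =
#' thinning) and the two-sided t-test p-value of the slope. This is the
#' pretest deciding between the covariance (trend) comparison and the
#' plain group-mean comparison.
#'
#' @param records data.frame with columns `age_weeks` and the metric.
#' @param metric metric column name, see [thickness_metrics()].
#' @return list with `slope`, `p_value`, `intercept`, `n`.
#' @export
fit_age_pretest <- function(records, metric = "total_whole") {
  if (!metric %in% names(records))
    stop_retoct(sprintf("metric '%s' not present in records", metric),
                "retoct_validation_error")
  y <- records[[metric]]; x <- records$age_weeks
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L || length(unique(x)) < 2L)
    stop_retoct("pretest needs >= 3 records with >= 2 distinct ages",
                "retoct_validation_error")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       p_value = unname(sm["x", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n = length(y))
}

#' Compare one thickness metric between two groups
#'
#' Runs the age-regression pretest in each group. If both pretests are
#' significant (p < alpha) the metric is compared by analysis of
#' covariance: the reported p-value is the F-test of the age-by-group
#' interaction (a difference in the thinning trend); the group effect of
#' the additive model (difference in age-adjusted means) is also reported
#' secondarily. If either pretest fails, a one-way ANOVA on the group
#' means is used instead.
#'
#' @param records data.frame with columns `group`, `age_weeks` and the
#'   metric (both groups stacked).
#' @param metric metric column name.
#' @param config a [pipeline_config()] (section `stats`).
#' @return a one-row data.frame: pretest slopes and p-values per group,
#'   `test` ("ANCOVA" or "ANOVA"), `p_value`, and `p_adjusted_means`
#'   (ANCOVA additive group effect; `NA` on the ANOVA branch).
#' @export
compare_groups <- function(records, metric = "total_whole",
                           config = pipeline_config()) {
  alpha <- config$stats$pretest_alpha
  gs <- sort(unique(records$group))
  if (length(gs) != 2L)
    stop_retoct("exactly two groups are required", "retoct_validation_error")
  pre <- lapply(gs, function(g)
    fit_age_pretest(records[records$group == g, , drop = FALSE], metric))
  names(pre) <- gs
  both_sig <- all(vapply(pre, function(p) p$p_value < alpha, logical(1L)))
  y <- records[[metric]]; x <- records$age_weeks
  grp <- factor(records$group, levels = gs)
  if (both_sig) {
    full <- stats::lm(y ~ x * grp)
    an <- stats::anova(full)
    p_int <- an["x:grp", "Pr(>F)"]
    addm <- stats::lm(y ~ x + grp)
    p_adj <- stats::anova(addm)["grp", "Pr(>F)"]
    test <- "ANCOVA"; p <- p_int
  } else {
    p <- stats::anova(stats::lm(y ~ grp))["grp", "Pr(>F)"]
    p_adj <- NA_real_
    test <- "ANOVA"
  }
  data.frame(metric = metric,
             pretest_p_1 = pre[[1L]]$p_value, pretest_p_2 = pre[[2L]]$p_value,
             slope_1 = pre[[1L]]$slope, slope_2 = pre[[2L]]$slope,
             group_1 = gs[1L], group_2 = gs[2L],
             test = test, p_value = p, p_adjusted_means = p_adj,
             stringsAsFactors = FALSE)
}

#' Compare all nine thickness metrics between groups
#'
#' @param records stacked cohort table (see [generate_cohort()] or
#'   [compute_thickness()] rows).
#' @param config a [pipeline_config()]. With `stats$bonferroni = TRUE` a
#'   Bonferroni-adjusted p-value column over the nine metrics is added.
#' @return data.frame with one row per metric.
#' @export
compare_all_metrics <- function(records, config = pipeline_config()) {
  out <- do.call(rbind, lapply(thickness_metrics(), compare_groups,
                               records = records, config = config))
  if (isTRUE(config$stats$bonferroni))
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
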