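# Cohort statistics: pre/post comparisons with a normality gate,
# change-between-groups, the univariable-screen Cox pipeline, intraobserver
# variability and post hoc power.

shapiro_normal <- function(x, alpha = 0.05) {
  # Shapiro-Wilk gate; constant or tiny samples are treated as non-normal
  # degenerate cases by the callers.
  if (length(x) < 3 || length(x) > 5000) x <- x[seq_len(min(length(x), 5000))]
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  !is.na(p) && p >= alpha
}

#' Paired pre/post change test with a normality gate
#'
#' Tests whether a parameter changed between the pre- and post-ablation
#' stage within patients. The paired differences are screened with
#' Shapiro-Wilk at alpha = 0.05: normal-looking differences use the paired
#' Student's t-test, otherwise the Wilcoxon signed-rank test.
#'
#' @param pre,post numeric vectors of paired per-patient values.
#' @param alpha_normality Shapiro-Wilk gate level, default 0.05.
#' @return list: `mean_change`, `statistic`, `p_value`, `test` (name of the
#'   test used), `n`, `degenerate` (TRUE when all changes are identical).
#' @export
paired_change_test <- function(pre, post, alpha_normality = 0.05) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 3) stop("need at least 3 paired observations")
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(mean_change = mean(d), statistic = NA_real_,
                p_value = if (all(d == 0)) 1 else NA_real_,
                test = "degenerate", n = length(d), degenerate = TRUE))
  }
  if (shapiro_normal(d, alpha_normality)) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    list(mean_change = mean(d), statistic = unname(tt$statistic),
         p_value = tt$p.value, test = "paired t", n = length(d),
         degenerate = FALSE)
  } else {
    wt <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)
    list(mean_change = mean(d), statistic = unname(wt$statistic),
         p_value = wt$p.value, test = "wilcoxon signed-rank", n = length(d),
         degenerate = FALSE)
  }
}

#' Compare parameter changes between outcome groups
#'
#' Unpaired comparison of per-patient changes between the failure and
#' success arms: Student's t-test when both groups pass the Shapiro-Wilk
#' gate, Mann-Whitney U otherwise. The difference is reported as
#' failure minus success.
#'
#' @param changes_success,changes_failure numeric vectors of per-patient
#'   changes in the two arms.
#' @param alpha_normality Shapiro-Wilk gate level, default 0.05.
#' @return list: `difference` (failure - success mean change), `statistic`,
#'   `p_value`, `test`, `n_success`, `n_failure`.
#' @export
between_group_change_test <- function(changes_success, changes_failure,
                                      alpha_normality = 0.05) {
  changes_success <- changes_success[!is.na(changes_success)]
  changes_failure <- changes_failure[!is.na(changes_failure)]
  if (length(changes_success) < 3 || length(changes_failure) < 3)
    stop("each group needs at least 3 observations")
  normal <- shapiro_normal(changes_success, alpha_normality) &&
    shapiro_normal(changes_failure, alpha_normality)
  if (normal) {
    tt <- stats::t.test(changes_failure, changes_success, var.equal = TRUE)
    list(difference = mean(changes_failure) - mean(changes_success),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         test = "unpaired t", n_success = length(changes_success),
         n_failure = length(changes_failure))
  } else {
    wt <- stats::wilcox.test(changes_failure, changes_success, exact = FALSE)
    list(difference = mean(changes_failure) - mean(changes_success),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         test = "mann-whitney", n_success = length(changes_success),
         n_failure = length(changes_failure))
  }
}

#' Compare a categorical variable between groups
#'
#' Pearson's chi-squared test, switching to Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param x,group factors (or vectors coercible to factors) of equal length.
#' @return list: `p_value`, `test`.
#' @export
compare_categorical <- function(x, group) {
  tab <- table(x, group)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p_value = stats::fisher.test(tab)$p.value, test = "fisher")
  } else {
    list(p_value = stats::chisq.test(tab, correct = FALSE)$p.value,
         test = "chi-squared")
  }
}

#' Univariable screen followed by multivariable Cox regression
#'
#' Fits one univariable Cox proportional-hazards model per candidate
#' covariate (Efron tie handling, as coarse event times produce many ties);
#' covariates with univariable Wald p below the threshold enter a single
#' multivariable model. Hazard ratios with 95% confidence intervals are
#' returned for both stages; screened-out covariates carry no multivariable
#' entry.
#'
#' @param cohort data frame with the covariates plus time and event columns.
#' @param covariates character vector of covariate column names.
#' @param threshold univariable screen p-value threshold, default 0.05.
#' @param time_col,event_col names of the follow-up time and 0/1 event
#'   columns, defaults `"event_time_months"` and `"event"`.
#' @param min_events minimum number of events required, default 10.
#' @return data frame with columns `term`, `stage` (`"univariable"` /
#'   `"multivariable"`), `hazard_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `selected` (passed the screen).
#' @export
cox_screen_and_fit <- function(cohort, covariates, threshold = 0.05,
                               time_col = "event_time_months",
                               event_col = "event", min_events = 10) {
  stopifnot(all(c(time_col, event_col, covariates) %in% names(cohort)))
  cc <- stats::complete.cases(cohort[, c(time_col, event_col, covariates)])
  cohort <- cohort[cc, ]
  if (sum(cohort[[event_col]]) < min_events)
    stop("fewer than ", min_events, " events: Cox model not fitted")
  surv <- survival::Surv(cohort[[time_col]], cohort[[event_col]])
  fit_one <- function(fm, terms, stage) {
    fit <- tryCatch(
      survival::coxph(fm, data = cohort, ties = "efron"),
      warning = function(w) stop("Cox model did not converge cleanly for ",
                                 paste(terms, collapse = " + "), ": ",
                                 conditionMessage(w)),
      error = function(e) stop("Cox model failed for ",
                               paste(terms, collapse = " + "), ": ",
                               conditionMessage(e)))
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    if (any(!is.finite(co[, "coef"])) || any(abs(co[, "coef"]) > 15))
      stop("separation suspected in Cox model for ",
           paste(terms, collapse = " + "))
    data.frame(term = rownames(co), stage = stage,
               hazard_ratio = unname(ci[, "exp(coef)"]),
               ci_low = unname(ci[, "lower .95"]),
               ci_high = unname(ci[, "upper .95"]),
               p_value = unname(co[, "Pr(>|z|)"]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  uni <- do.call(rbind, lapply(covariates, function(v)
    fit_one(stats::reformulate(v, response = "surv"), v, "univariable")))
  uni$selected <- uni$p_value < threshold
  sel <- covariates[vapply(covariates, function(v)
    any(uni$term == v & uni$selected), TRUE)]
  # covariates whose model terms are expansions (factors) are matched by name
  if (!length(sel)) {
    sel <- covariates[vapply(covariates, function(v)
      any(startsWith(uni$term, v) & uni$selected), TRUE)]
  }
  multi <- NULL
  if (length(sel) > 0) {
    multi <- fit_one(stats::reformulate(sel, response = "surv"), sel,
                     "multivariable")
    multi$selected <- TRUE
  }
  out <- rbind(uni, multi)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_events") <- sum(cohort[[event_col]])
  out
}

#' Intraobserver variability between two annotation passes
#'
#' For each parameter column present in both passes: the mean and SD of the
#' absolute per-record difference, and the percent variability, i.e. the
#' mean absolute difference as a percentage of the (absolute) grand mean of
#' the parameter over both passes.
#'
#' @param pass1,pass2 data frames of repeated measurements with a shared
#'   `id` column and identical parameter columns.
#' @param id_col key column name, default `"id"`.
#' @return data frame: `parameter`, `mean_abs_diff`, `sd_abs_diff`,
#'   `percent_variability`.
#' @export
intraobserver_variability <- function(pass1, pass2, id_col = "id") {
  if (!id_col %in% names(pass1) || !id_col %in% names(pass2))
    stop("both passes need an `", id_col, "` column")
  if (!setequal(pass1[[id_col]], pass2[[id_col]]) ||
      anyDuplicated(pass1[[id_col]]) || anyDuplicated(pass2[[id_col]]))
    stop("the two passes must cover the same records exactly once")
  pass2 <- pass2[match(pass1[[id_col]], pass2[[id_col]]), ]
  params <- setdiff(intersect(names(pass1), names(pass2)), id_col)
  params <- params[vapply(params, function(p) is.numeric(pass1[[p]]), TRUE)]
  if (!length(params)) stop("no shared numeric parameter columns")
  out <- do.call(rbind, lapply(params, function(p) {
    d <- abs(pass1[[p]] - pass2[[p]])
    gm <- mean(c(pass1[[p]], pass2[[p]]))
    data.frame(parameter = p, mean_abs_diff = mean(d),
               sd_abs_diff = stats::sd(d),
               percent_variability = if (abs(gm) > 0) mean(d) / abs(gm) * 100
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Post hoc power for a two-sample t-test
#'
#' Power of the two-sided two-sample t-test by the standard noncentral-t
#' formulation, allowing unequal group sizes: noncentrality
#' d * sqrt(n1 n2 / (n1 + n2)) with n1 + n2 - 2 degrees of freedom.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param effect_size standardized mean difference (Cohen's d).
#' @param alpha two-sided significance level, default 0.05.
#' @return power in \[0, 1\].
#' @export
posthoc_power <- function(n1, n2, effect_size, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- effect_size * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}
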