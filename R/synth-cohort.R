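# Synthetic post-ablation cohort generator.
#
# Patients are assigned to an intended arm (success / failure of pulmonary
# vein isolation); the arm drives the pre/post distributions of the four
# P-wave parameters (defaults are the study-group means and SDs). Recurrence
# events follow an exponential proportional-hazards law with log-linear
# effects of the standardized PWDc and PWA changes; events during the
# 3-month blanking window do not count as failure (implemented via the
# memoryless restart at the end of blanking), and follow-up is censored at
# the horizon. The realized `outcome` column derives from the event process.

default_param_distributions <- function() {
  # group means/SDs for pre- and post-ablation stages; PTFV1 SDs are not
  # reported and use 1.0 mm.s.
  list(
    pwdc_ms = list(success = list(pre = c(132, 12), post = c(132, 11)),
                   failure = list(pre = c(139, 10), post = c(146, 9))),
    pwa_mV = list(success = list(pre = c(1.6, 0.03), post = c(1.8, 0.04)),
                  failure = list(pre = c(1.6, 0.04), post = c(2.0, 0.1))),
    pwdisp_ms = list(success = list(pre = c(31, 0.5), post = c(32, 0.5)),
                     failure = list(pre = c(36, 0.8), post = c(38, 0.8))),
    ptfv1_mms = list(success = list(pre = c(-3.4, 1.0), post = c(-4.6, 1.0)),
                     failure = list(pre = c(-3.4, 1.0), post = c(-5.4, 1.0))))
}

#' Specification for a synthetic ablation cohort
#'
#' @param n_success,n_failure intended-arm sizes (defaults 130 and 50).
#' @param params nested list of per-parameter, per-group, per-stage
#'   `c(mean, sd)` pairs; see `pwavePVI:::default_param_distributions()`.
#' @param log_hr_pwdc,log_hr_pwa log-hazard coefficients on the
#'   standardized PWDc and PWA changes (defaults 0.9 and 0.5, i.e. hazard
#'   ratios about 2.5 and 1.7 per SD).
#' @param baseline_hazard baseline event rate, events/month (default 0.025).
#' @param horizon_months follow-up horizon (default 12).
#' @param blanking_months blanking window during which recurrences are not
#'   counted as failure (default 3).
#' @param seed integer RNG seed.
#' @return a `synth_cohort_spec` list.
#' @export
synth_cohort_spec <- function(n_success = 130, n_failure = 50,
                              params = default_param_distributions(),
                              log_hr_pwdc = 0.9, log_hr_pwa = 0.5,
                              baseline_hazard = 0.025, horizon_months = 12,
                              blanking_months = 3, seed = 1L) {
  if (n_success < 2 || n_failure < 2)
    stop("each group needs at least 2 patients")
  if (!(horizon_months > blanking_months && blanking_months >= 0))
    stop("must have horizon > blanking >= 0")
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0)
    stop("degenerate baseline hazard")
  sds <- unlist(lapply(params, function(p) lapply(p, function(g)
    vapply(g, `[`, 0, 2))))
  if (any(sds < 0)) stop("all parameter SDs must be >= 0")
  structure(list(n_success = n_success, n_failure = n_failure,
                 params = params, log_hr_pwdc = log_hr_pwdc,
                 log_hr_pwa = log_hr_pwa, baseline_hazard = baseline_hazard,
                 horizon_months = horizon_months,
                 blanking_months = blanking_months, seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

# Population mean and SD of the post-pre change for one parameter under the
# mixture of the two intended arms (stages drawn independently).
change_moments <- function(par, n_s, n_f) {
  w <- c(success = n_s, failure = n_f) / (n_s + n_f)
  mu <- vapply(c("success", "failure"), function(g)
    par[[g]]$post[1] - par[[g]]$pre[1], 0)
  v <- vapply(c("success", "failure"), function(g)
    par[[g]]$post[2] ^ 2 + par[[g]]$pre[2] ^ 2, 0)
  m <- sum(w * mu)
  list(mean = m, sd = sqrt(sum(w * (v + mu ^ 2)) - m ^ 2))
}

draw_covariates <- function(n) {
  # Null covariates with physiologically plausible distributions (no effect
  # on the hazard); binary flags as 0/1.
  data.frame(
    age = stats::rnorm(n, 60, 10),
    male = stats::rbinom(n, 1, 0.71),
    hypertension = stats::rbinom(n, 1, 0.36),
    diabetes = stats::rbinom(n, 1, 0.11),
    ccf = stats::rbinom(n, 1, 0.07),
    ihd = stats::rbinom(n, 1, 0.08),
    cve = stats::rbinom(n, 1, 0.08),
    bmi = stats::rnorm(n, 22.2, 3.1),
    chads_vasc = pmax(0, round(stats::rnorm(n, 2, 1))),
    osa = stats::rbinom(n, 1, 0.12),
    thyroid = stats::rbinom(n, 1, 0.15),
    potassium = stats::rnorm(n, 4.1, 0.5),
    calcium = stats::rnorm(n, 2.3, 0.15),
    magnesium = stats::rnorm(n, 0.9, 0.15),
    lvef = stats::rnorm(n, 51, 8),
    la_volume_indexed = stats::rnorm(n, 30.2, 4),
    rf_ablation = stats::rbinom(n, 1, 0.30),
    sotalol = stats::rbinom(n, 1, 0.31),
    bisoprolol = stats::rbinom(n, 1, 0.90),
    aad_stop_months = pmin(12, pmax(0, stats::rnorm(n, 6.3, 1.5))))
}

#' Generate a synthetic cohort of patient records
#'
#' @param spec a [synth_cohort_spec()].
#' @return data frame with one row per patient: `id`, `group` (intended
#'   arm), pre/post values of the four parameters (`pwdc_pre`, `pwdc_post`,
#'   ...), their changes (`pwdc_change`, ...), standardized changes
#'   (`z_pwdc_change`, `z_pwa_change`, standardized by the generator's
#'   population moments), the null covariates, `event_time_months`,
#'   `event` (0/1, recurrences after the blanking window only) and the
#'   realized `outcome` (`"failure"` iff `event == 1`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  n <- spec$n_success + spec$n_failure
  group <- rep(c("success", "failure"), c(spec$n_success, spec$n_failure))
  with_seed(spec$seed, {
    draw <- function(param) {
      vapply(seq_len(n), function(i) {
        ms <- spec$params[[param]][[group[i]]]
        c(stats::rnorm(1, ms$pre[1], ms$pre[2]),
          stats::rnorm(1, ms$post[1], ms$post[2]))
      }, c(0, 0))
    }
    vals <- lapply(stats::setNames(nm = names(spec$params)), draw)
    cov <- draw_covariates(n)
    df <- data.frame(id = sprintf("P%03d", seq_len(n)), group = group,
                     stringsAsFactors = FALSE)
    for (p in names(vals)) {
      base <- sub("_(ms|mV|mms)$", "", p)
      df[[paste0(base, "_pre")]] <- vals[[p]][1, ]
      df[[paste0(base, "_post")]] <- vals[[p]][2, ]
      df[[paste0(base, "_change")]] <- vals[[p]][2, ] - vals[[p]][1, ]
    }
    mom_d <- change_moments(spec$params$pwdc_ms, spec$n_success, spec$n_failure)
    mom_a <- change_moments(spec$params$pwa_mV, spec$n_success, spec$n_failure)
    df$z_pwdc_change <- (df$pwdc_change - mom_d$mean) / mom_d$sd
    df$z_pwa_change <- (df$pwa_change - mom_a$mean) / mom_a$sd
    df <- cbind(df, cov)
    rate <- spec$baseline_hazard *
      exp(spec$log_hr_pwdc * df$z_pwdc_change +
            spec$log_hr_pwa * df$z_pwa_change)
    if (any(!is.finite(rate)))
      stop("degenerate hazard: non-finite event rate")
    # recurrences during blanking are not failures; by memorylessness of the
    # exponential law, the first countable event occurs blanking + Exp(rate)
    t_event <- spec$blanking_months + stats::rexp(n, rate)
    df$event <- as.integer(t_event <= spec$horizon_months)
    df$event_time_months <- pmin(t_event, spec$horizon_months)
    df$outcome <- ifelse(df$event == 1, "failure", "success")
    df
  })
}
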