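#!/usr/bin/env Rscript
# Stage 3: the cohort statistics.
#
# On the simulated cohort from stage 1: paired pre/post change tests within
# each arm (Shapiro-Wilk gate choosing paired t vs Wilcoxon), the
# between-arm comparison of changes, and the Cox proportional-hazards
# pipeline with the univariable screen (p < 0.05) feeding the multivariable
# model. Results are written as tidy CSV tables.

suppressPackageStartupMessages(library(pwavePVI))
if (!file.exists("results/cohort.csv"))
  stop("run analysis/01_simulate_cohort.R first")
cohort <- read.csv("results/cohort.csv")

params <- c(pwdc = "PWDc (ms)", pwa = "PWA", pwdisp = "PWDisp (ms)",
            ptfv1 = "PTFV1 (mm.s)")
change_rows <- list()
for (p in names(params)) {
  for (g in c("success", "failure")) {
    rows <- cohort[cohort$group == g, ]
    r <- paired_change_test(rows[[paste0(p, "_pre")]],
                            rows[[paste0(p, "_post")]])
    change_rows[[length(change_rows) + 1]] <- data.frame(
      parameter = p, group = g, mean_change = r$mean_change,
      p_value = r$p_value, test = r$test)
  }
  b <- between_group_change_test(
    cohort[[paste0(p, "_change")]][cohort$group == "success"],
    cohort[[paste0(p, "_change")]][cohort$group == "failure"])
  change_rows[[length(change_rows) + 1]] <- data.frame(
    parameter = p, group = "failure - success", mean_change = b$difference,
    p_value = b$p_value, test = b$test)
}
changes <- do.call(rbind, change_rows)
write.csv(changes, "results/change_tests.csv", row.names = FALSE)
cat("Pre/post and between-arm change tests:\n")
print(changes, digits = 3, row.names = FALSE)

cohort$z_pwdc_sample <- as.numeric(scale(cohort$pwdc_change))
cohort$z_pwa_sample <- as.numeric(scale(cohort$pwa_change))
covs <- c("z_pwdc_sample", "z_pwa_sample", "pwdisp_change", "ptfv1_change",
          "age", "male", "diabetes", "hypertension", "ccf", "cve",
          "chads_vasc", "thyroid", "osa", "potassium", "calcium",
          "magnesium", "lvef", "la_volume_indexed", "rf_ablation",
          "sotalol", "bisoprolol", "aad_stop_months")
cox <- cox_screen_and_fit(cohort, covs, threshold = 0.05)
write.csv(cox, "results/cox_results.csv", row.names = FALSE)
cat(sprintf("\nCox screen: %d of %d covariates passed p < 0.05:\n",
            sum(cox$selected[cox$stage == "univariable"]), length(covs)))
print(cox[cox$stage == "multivariable",
          c("term", "hazard_ratio", "ci_low", "ci_high", "p_value")],
      digits = 3, row.names = FALSE)
cat("\nFull table in results/cox_results.csv\n")
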