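test_that("paired change test handles degenerate and clear-cut inputs", {
  pre <- c(130, 132, 128, 131, 135)
  same <- paired_change_test(pre, pre)
  expect_equal(same$mean_change, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_error(paired_change_test(1:2, 2:3), "at least 3")

  set.seed(61)
  pre2 <- rnorm(50, 139, 10)
  post2 <- pre2 + rnorm(50, 7, 3)
  res <- paired_change_test(pre2, post2)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$mean_change, 7, tolerance = 0.3)
})

test_that("paired test maintains nominal type-I error under the null", {
  set.seed(62)
  p <- replicate(1000, paired_change_test(rnorm(30), rnorm(30))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("paired test detects the failure-group change at n = 50", {
  hits <- vapply(1:50, function(i) {
    co <- generate_cohort(synth_cohort_spec(n_success = 2, n_failure = 50,
                                            seed = 100 + i))
    f <- co[co$group == "failure", ]
    paired_change_test(f$pwdc_pre, f$pwdc_post)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("between-group change test is antisymmetric and well calibrated", {
  set.seed(63)
  a <- rnorm(50); b <- rnorm(50, 1)
  r1 <- between_group_change_test(a, b)
  r2 <- between_group_change_test(b, a)
  expect_equal(r1$difference, -r2$difference)
  p <- replicate(500, between_group_change_test(rnorm(40), rnorm(40))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.075)
  # null p-values approximately uniform (the Wilcoxon branch makes them
  # mildly discrete, so check the empirical CDF on a coarse grid)
  grid <- seq(0.1, 0.9, by = 0.2)
  ecdf_p <- ecdf(p)(grid)
  expect_true(all(abs(ecdf_p - grid) < 0.06))
})

test_that("between-group test has power for a 5 ms shift at n 50/130", {
  set.seed(64)
  hits <- replicate(100,
    between_group_change_test(rnorm(130, 0, 1),
                              rnorm(50, 5, 1))$p_value < 0.001)
  expect_gte(mean(hits), 0.99)
})

test_that("categorical comparisons switch to Fisher for sparse tables", {
  set.seed(65)
  x <- rbinom(200, 1, 0.5); g <- rbinom(200, 1, 0.5)
  expect_equal(compare_categorical(x, g)$test, "chi-squared")
  xs <- c(rep(1, 3), rep(0, 17)); gs <- rep(c(0, 1), 10)
  expect_equal(compare_categorical(xs, gs)$test, "fisher")
})

test_that("the univariable screen feeds only significant covariates forward", {
  co <- generate_cohort(synth_cohort_spec(seed = 66))
  res <- cox_screen_and_fit(co, c("z_pwdc_change", "z_pwa_change", "age",
                                  "male", "lvef"))
  uni <- res[res$stage == "univariable", ]
  multi <- res[res$stage == "multivariable", ]
  expect_setequal(multi$term, uni$term[uni$selected])
  expect_true(all(res$ci_low <= res$hazard_ratio + 1e-12))
  expect_true(all(res$hazard_ratio <= res$ci_high + 1e-12))
  expect_true(all(res$hazard_ratio > 0))
  expect_true("z_pwdc_change" %in% multi$term)
})

test_that("null covariates yield hazard ratios near 1 at large n", {
  co <- generate_cohort(synth_cohort_spec(n_success = 1500, n_failure = 500,
                                          log_hr_pwdc = 0, log_hr_pwa = 0,
                                          seed = 67))
  res <- cox_screen_and_fit(co, c("age", "bmi"), threshold = 1e-9)
  uni <- res[res$stage == "univariable", ]
  # standardize: age SD 10 years, bmi SD 3.1 -> per-unit HR very close to 1
  expect_true(all(uni$hazard_ratio > 0.97 & uni$hazard_ratio < 1.03))
})

test_that("log hazard-ratio bias shrinks as the cohort grows", {
  est <- vapply(c(100, 400, 1600), function(n) {
    b <- vapply(1:20, function(i) {
      co <- generate_cohort(synth_cohort_spec(
        n_success = round(n * 130 / 180), n_failure = round(n * 50 / 180),
        seed = 1000 * n + i))
      co$z <- (co$pwdc_change - mean(co$pwdc_change)) / sd(co$pwdc_change)
      fit <- survival::coxph(
        survival::Surv(event_time_months, event) ~ z, data = co,
        ties = "efron")
      unname(coef(fit))
    }, 0)
    mean(b) - 0.9
  }, 0)
  expect_lt(abs(est[3]), abs(est[1]) + 0.05)
  expect_lt(abs(est[3]), 0.1)
})

test_that("Cox fits with too few events are refused", {
  co <- generate_cohort(synth_cohort_spec(seed = 68))
  co$event <- 0L
  expect_error(cox_screen_and_fit(co, "age"), "events")
})

test_that("intraobserver variability matches its arithmetic definition", {
  m1 <- data.frame(id = sprintf("E%02d", 1:22), pwd_ms = rnorm(22, 100, 5))
  same <- intraobserver_variability(m1, m1)
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$sd_abs_diff, 0)
  expect_equal(same$percent_variability, 0)

  m2 <- m1; m2$pwd_ms <- m1$pwd_ms + 2
  shifted <- intraobserver_variability(m1, m2)
  expect_equal(shifted$mean_abs_diff, 2)
  expect_equal(shifted$sd_abs_diff, 0)
  expect_equal(shifted$percent_variability,
               2 / mean(c(m1$pwd_ms, m2$pwd_ms)) * 100)
  expect_error(intraobserver_variability(m1, m2[1:10, ]), "same records")
})

test_that("re-annotation jitter follows the folded-normal expectation", {
  set.seed(71)
  m1 <- data.frame(id = seq_len(1000), pwd_ms = rnorm(1000, 100, 5))
  m2 <- m1; m2$pwd_ms <- m1$pwd_ms + rnorm(1000, 0, 3)
  v <- intraobserver_variability(m1, m2)
  expect_equal(v$mean_abs_diff, 3 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("post hoc power follows the noncentral-t benchmark", {
  expect_equal(posthoc_power(50, 50, 0, 0.05), 0.05, tolerance = 1e-8)
  expect_equal(posthoc_power(64, 64, 0.5, 0.05), 0.80, tolerance = 0.01)
  # cross-check against the equal-n closed form in stats
  ref <- power.t.test(n = 64, delta = 0.5, sd = 1)$power
  expect_equal(posthoc_power(64, 64, 0.5), ref, tolerance = 1e-3)
  # monotone in effect size and n
  expect_true(all(diff(vapply(c(0.2, 0.4, 0.6, 0.8),
                              function(d) posthoc_power(40, 40, d), 0)) > 0))
  expect_true(all(diff(vapply(c(20, 40, 80),
                              function(n) posthoc_power(n, n, 0.5), 0)) > 0))
  expect_error(posthoc_power(50, 50, 0.5, alpha = 2), "alpha")
  expect_error(posthoc_power(1, 50, 0.5), "sizes")
})
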