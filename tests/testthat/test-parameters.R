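test_that("Hodges correction is the stated linear form", {
  expect_equal(correct_pwd_hodges(120, 60), 120)
  expect_equal(correct_pwd_hodges(120, 80), 155)
  expect_equal(correct_pwd_hodges(140, 50), 122.5)
  expect_error(correct_pwd_hodges(120, 300), "heart rate")
  expect_error(correct_pwd_hodges(-5, 70), "positive")
})

test_that("Hodges correction is strictly increasing in heart rate", {
  set.seed(51)
  pwd <- runif(1000, 60, 200)
  hr <- runif(1000, 30, 240)
  expect_equal(correct_pwd_hodges(pwd, 60), pwd)
  dc <- correct_pwd_hodges(pwd, hr + 1) - correct_pwd_hodges(pwd, hr - 1)
  expect_true(all(dc > 0))
})

test_that("per-lead PWD and PWA summaries follow the stated conventions", {
  expect_equal(summarize_pwd(rep(130, 12)), 130)
  expect_equal(summarize_pwd(seq(110, 140, length.out = 12)), 140)
  expect_equal(summarize_pwd(c(NA, 125, NA)), 125)
  expect_equal(summarize_pwd(c(110, 130), rule = "mean"), 120)
  expect_error(summarize_pwd(c(NA_real_, NA_real_)), "no measurable")
  expect_equal(compute_pwa(c(0.1, 0.15, 0.2)), 0.2)
  expect_equal(compute_pwa(c(0.1, -0.25)), 0.25)
  expect_equal(compute_pwa(rep(0, 5)), 0)
})

test_that("dispersion is the max-min spread, shift- and order-invariant", {
  expect_equal(compute_pwdisp(c(120, 120, 120)), 0)
  expect_equal(compute_pwdisp(c(110, 125, 140)), 30)
  expect_equal(compute_pwdisp(c(140, 110, 125)), 30)
  expect_equal(compute_pwdisp(c(110, 125, 140) + 17), 30)
  expect_error(compute_pwdisp(120), "2 measurable")
})

test_that("PTFV1 is the signed amplitude-duration product", {
  # -0.1 mV is 1 mm at 0.1 mV/mm; 40 ms = 0.04 s
  expect_equal(compute_ptfv1(-0.1, 40), -0.04)
  expect_equal(compute_ptfv1(-0.1, 80), -0.08)  # linear in duration
  expect_equal(compute_ptfv1(-0.2, 40), -0.08)  # linear in amplitude
  expect_equal(compute_ptfv1(0.05, 0), 0)       # monophasic positive P
  expect_equal(compute_ptfv1(-0.1, 40, scale = 10), -0.4)
  expect_error(compute_ptfv1(NA, 40), "absent")
})

test_that("full parameter sets are recovered from clean records", {
  ps <- compute_parameter_set(
    preprocess(generate_ecg(clean_record(hr = 60, d_ms = 120))$record))
  expect_equal(ps$pwdc_ms, 120, tolerance = 4 / 120)
  expect_lte(ps$pwdisp_ms, 4)
  expect_equal(ps$heart_rate_bpm, 60, tolerance = 0.01)
  expect_equal(ps$leads_used, 12)

  ps90 <- compute_parameter_set(
    preprocess(generate_ecg(clean_record(hr = 90, d_ms = 120))$record))
  expect_equal(ps90$pwdc_ms, 172.5, tolerance = 5 / 172.5)

  # determinism: the same record yields identical parameter sets
  rec <- preprocess(generate_ecg(synth_ecg_spec(duration_s = 25, seed = 3))$record)
  a <- compute_parameter_set(rec, stage = "pre")
  b <- compute_parameter_set(rec, stage = "post")
  expect_equal(a$pwdc_ms, b$pwdc_ms)
  expect_equal(a$ptfv1_mms, b$ptfv1_mms)
})

test_that("lead II amplitude is recovered through the full pipeline", {
  amps <- stats::setNames(0.15 * pwavePVI:::P_AMP_PATTERN[ECG_LEADS],
                          ECG_LEADS)
  amps["II"] <- 0.18
  spec <- synth_ecg_spec(heart_rate_bpm = 60, duration_s = 25,
                         p_amplitude_mV = amps, noise_sd_mV = 0,
                         baseline_wander_amplitude_mV = 0, seed = 2)
  ps <- compute_parameter_set(preprocess(generate_ecg(spec)$record))
  expect_equal(ps$pwa_mV, 0.18, tolerance = 0.01 / 0.18)
})

test_that("PTFV1 is recovered from the biphasic V1 ground truth", {
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, biphasic = 0.4,
                                   duration_s = 25))
  ps <- compute_parameter_set(preprocess(gen$record))
  v1 <- gen$fiducials[gen$fiducials$lead == "V1", ]
  analytic <- -mean(abs(v1$neg_peak_mV)) / 0.1 * mean(v1$neg_duration_ms) / 1000
  expect_lt(ps$ptfv1_mms, 0)
  expect_equal(ps$ptfv1_mms, analytic, tolerance = 0.15)
})

test_that("pipeline PWDc tracks the analytic value over the duration-rate grid", {
  for (d_ms in c(100, 140)) for (hr in c(60, 90)) {
    rec <- preprocess(generate_ecg(clean_record(hr = hr, d_ms = d_ms))$record)
    ps <- compute_parameter_set(rec)
    expect_lt(abs(ps$pwdc_ms - (d_ms + 1.75 * (hr - 60))), 5,
              label = sprintf("PWDc error at %d ms / %d bpm", d_ms, hr))
  }
})
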