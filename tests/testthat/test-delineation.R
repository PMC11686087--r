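test_that("beat detection recovers the beat schedule and heart rate", {
  gen <- generate_ecg(synth_ecg_spec(heart_rate_bpm = 60, duration_s = 60,
                                     seed = 21))
  rp <- detect_beats(preprocess(gen$record))
  expect_true(all(vapply(rp, length, 0L) >= 59 &
                    vapply(rp, length, 0L) <= 61))
  gen80 <- generate_ecg(synth_ecg_spec(heart_rate_bpm = 80, duration_s = 30,
                                       seed = 22))
  rp80 <- detect_beats(preprocess(gen80$record))
  expect_equal(mean(diff(rp80$II)) / 500 * 1000, 750, tolerance = 2 / 750)
  expect_equal(heart_rate_bpm(rp80$II, 500), 80, tolerance = 0.01)

  flat <- matrix(0, 1000, 12, dimnames = list(NULL, ECG_LEADS))
  expect_error(detect_beats(ecg_record(flat, 500)), "flat signal")
})

test_that("baseline estimation is unbiased, equivariant, and noise-robust", {
  x <- rep(0, 1000)
  expect_equal(estimate_baseline(x, 1:500), 0)
  expect_equal(estimate_baseline(x + 0.2, 1:500),
               estimate_baseline(x, 1:500) + 0.2)
  set.seed(31)
  xn <- rnorm(500, 0, 0.02)
  expect_lt(abs(estimate_baseline(xn, 1:500, "tp_segment_median")), 0.01)
  expect_error(estimate_baseline(x, integer(0)), "empty")
})

test_that("P-peak detection ignores narrow spikes and flags empty windows", {
  fs <- 500
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, duration_s = 12))
  f <- gen$fiducials[gen$fiducials$lead == "II" & gen$fiducials$beat == 4, ]
  x <- gen$record$samples[, "II"]
  win <- seq(f$t_end + 1L, f$r - 20L)
  pk <- detect_p_peak(x, win, 0, fs)
  expect_lte(abs(pk - f$p_peak), 1)

  # a 10 ms spike taller than the P must be rejected by the width filter
  spike_at <- f$p_onset - 100L
  xs <- x
  idx <- spike_at + seq_len(5)
  xs[idx] <- 0.5 * sin(pi * seq_len(5) / 6)
  expect_lte(abs(detect_p_peak(xs, win, 0, fs) - f$p_peak), 1)

  # pure baseline window: no excursion wide enough
  empty <- seq(f$t_end + 10L, f$p_onset - 10L)
  expect_true(is.na(detect_p_peak(x, empty, 0, fs)))
})

test_that("chord-rule onset matches the brute-force oracle exactly", {
  for (seed in 1:100) {
    b <- random_beat(seed)
    got <- detect_p_onset(b$x, b$t_end, b$p_peak)
    oracle <- brute_force_chord_onset(b$x, b$t_end, b$p_peak, "max")
    expect_identical(got, oracle$index)
    lit <- detect_p_onset(b$x, b$t_end, b$p_peak, "chord_min_distance_literal")
    oracle_min <- brute_force_chord_onset(b$x, b$t_end, b$p_peak, "min")
    expect_identical(lit, oracle_min$index)
  }
})

test_that("onset on a clean beat lands at the template foot; ramps degenerate", {
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, duration_s = 12))
  f <- gen$fiducials[gen$fiducials$lead == "II" & gen$fiducials$beat == 5, ]
  x <- gen$record$samples[, "II"]
  on <- detect_p_onset(x, f$t_end, f$p_peak)
  expect_lte(abs(on - f$p_onset), 2)
  # a signal that IS the chord has all distances zero
  ramp <- seq(0, 1, length.out = 100)
  expect_true(is.na(detect_p_onset(ramp, 1L, 100L)))
})

test_that("offset returns to baseline on clean beats and clamps otherwise", {
  fs <- 500
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, duration_s = 12))
  f <- gen$fiducials[gen$fiducials$lead == "II" & gen$fiducials$beat == 5, ]
  x <- gen$record$samples[, "II"]
  off <- detect_p_offset(x, f$p_peak, f$r - 20L, 0, fs)
  expect_false(off$clamped)
  expect_lte(abs(off$index - f$p_offset), 2)

  # a P riding into the QRS with no baseline return is clamped and flagged
  ramp_up <- c(rep(0, 50), seq(0, 0.2, length.out = 150))
  off2 <- detect_p_offset(ramp_up, 100L, 200L, 0, fs)
  expect_true(off2$clamped)
  expect_equal(off2$index, 200L)

  # symmetric P: peak-to-offset approximately equals onset-to-peak
  n <- 60
  sym <- c(rep(0, 100), 0.2 * 0.5 * (1 - cos(2 * pi * (1:n) / n)), rep(0, 100))
  pk <- which.max(sym)
  on <- detect_p_onset(sym + rnorm(length(sym), 0, 1e-5), 10L, pk)
  off3 <- detect_p_offset(sym, pk, length(sym) - 5L, 0, fs)
  expect_lte(abs((off3$index - pk) - (pk - on)), 6)
})

test_that("delineated fiducials keep the onset <= peak <= offset ordering", {
  gen <- generate_ecg(synth_ecg_spec(heart_rate_bpm = 72, duration_s = 20,
                                     seed = 23))
  fd <- delineate_record(preprocess(gen$record))
  m <- fd[fd$measurable, ]
  expect_gt(nrow(m), 100)
  expect_true(all(m$p_onset <= m$p_peak))
  expect_true(all(m$p_peak <= m$p_offset))
  expect_true(all(m$t_end < m$p_onset))
  expect_true(all(m$p_offset <= m$next_r))
})

test_that("delineation matches generator truth within 4 ms on clean records", {
  for (d_ms in c(80, 120, 160)) for (hr in c(50, 75, 110)) {
    gen <- generate_ecg(clean_record(hr = hr, d_ms = d_ms, duration_s = 20,
                                     biphasic = 0.4))
    fd <- delineate_record(gen$record)
    m <- merge(fd[fd$measurable, ], gen$fiducials, by = c("lead", "beat"))
    err <- m$pwd_ms - (m$p_offset.y - m$p_onset.y) / 500 * 1000
    expect_lt(max(abs(err)), 4.001,
              label = sprintf("max |PWD error| at %d ms / %d bpm", d_ms, hr))
  }
})

test_that("delaying the whole record shifts all fiducials by exactly k", {
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, duration_s = 15))
  k <- 37L
  shifted <- rbind(matrix(0, k, 12, dimnames = list(NULL, ECG_LEADS)),
                   gen$record$samples[1:(nrow(gen$record$samples) - k), ])
  rec_s <- ecg_record(shifted, 500)
  fd0 <- delineate_record(gen$record)
  fd1 <- delineate_record(rec_s)
  m0 <- fd0[fd0$measurable & fd0$beat %in% 2:10, ]
  m1 <- fd1[fd1$measurable & fd1$beat %in% 2:10, ]
  expect_equal(m1$p_onset, m0$p_onset + k)
  expect_equal(m1$p_peak, m0$p_peak + k)
  expect_equal(m1$p_offset, m0$p_offset + k)
})

test_that("averaging uses the first run of n consecutive measurable beats", {
  beats <- data.frame(pwd_ms = rep(c(118, 122), 10),
                      pwa_mV = rep(0.15, 20),
                      neg_duration_ms = 0, neg_peak_mV = 0,
                      measurable = TRUE)
  av <- average_measurements(beats, 20)
  expect_equal(av$pwd_ms, 120)
  expect_equal(av$n_beats_used, 20)
  # identical beats average to any single beat
  same <- beats; same$pwd_ms <- 130
  expect_equal(average_measurements(same, 20)$pwd_ms, 130)
  # a gap inside the run postpones the start; shortfall errors are named
  gap <- beats; gap$measurable[10] <- FALSE
  expect_error(average_measurements(gap, 20), "10")
  long <- rbind(gap, beats)
  expect_equal(average_measurements(long, 20)$n_beats_used, 20)
})

test_that("averaging noise scales as sigma over sqrt(n)", {
  set.seed(41)
  sds <- replicate(300, {
    b <- data.frame(pwd_ms = 120 + rnorm(20, 0, 3), pwa_mV = 0.15,
                    neg_duration_ms = 0, neg_peak_mV = 0, measurable = TRUE)
    average_measurements(b, 20)$pwd_ms
  })
  expect_equal(sd(sds), 3 / sqrt(20), tolerance = 0.15)
})

test_that("manual fiducial overrides replace indices and recompute durations", {
  gen <- generate_ecg(clean_record(hr = 60, d_ms = 120, duration_s = 12))
  fd <- delineate_record(gen$record)
  row <- fd[fd$lead == "II" & fd$beat == 3, ]
  ov <- data.frame(lead = "II", beat = 3, field = "p_onset",
                   index = row$p_onset - 5L)
  fd2 <- apply_fiducial_overrides(fd, gen$record, ov)
  row2 <- fd2[fd2$lead == "II" & fd2$beat == 3, ]
  expect_equal(row2$p_onset, row$p_onset - 5L)
  expect_equal(row2$pwd_ms, row$pwd_ms + 10)
})
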