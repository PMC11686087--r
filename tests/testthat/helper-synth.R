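# Shared fixture builders for the test suite. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

# A clean (noise- and wander-free) single-morphology record: uniform P
# duration in all leads, monophasic V1 unless asked otherwise.
clean_record <- function(hr = 60, d_ms = 120, duration_s = 25,
                         biphasic = 0, seed = 1, fs = 500) {
  synth_ecg_spec(heart_rate_bpm = hr, duration_s = duration_s,
                 sampling_rate_hz = fs, p_duration_ms = d_ms,
                 p_duration_uniform = TRUE, v1_biphasic_fraction = biphasic,
                 noise_sd_mV = 0, baseline_wander_amplitude_mV = 0,
                 seed = seed)
}

# Ground-truth P-wave span in ms for a generated record, per lead/beat.
truth_pwd_ms <- function(gen, fs = 500) {
  (gen$fiducials$p_offset - gen$fiducials$p_onset) / fs * 1000
}

# Brute-force point-to-chord distance oracle: scans every sample with the
# scalar geometric formula, independently of the vectorized implementation.
brute_force_chord_onset <- function(x, i1, i2, rule = "max") {
  best_j <- NA_integer_
  best_d <- if (rule == "max") -Inf else Inf
  for (j in seq(i1 + 1L, i2 - 1L)) {
    dx <- i2 - i1
    dy <- x[i2] - x[i1]
    d <- abs(dy * (j - i1) - dx * (x[j] - x[i1])) / sqrt(dx^2 + dy^2)
    better <- if (rule == "max") d > best_d else d < best_d
    if (better) { best_d <- d; best_j <- j }
  }
  list(index = best_j, distance = best_d)
}

# One random synthetic beat for onset-oracle comparisons: baseline segment,
# then a smooth rising P, with mild noise so the arg max is unique.
random_beat <- function(seed) {
  set.seed(seed)
  fs <- 500
  base_len <- sample(50:250, 1)
  rise_len <- sample(20:60, 1)
  amp <- runif(1, 0.05, 0.3)
  x <- c(rep(0, base_len),
         amp * 0.5 * (1 - cos(pi * seq_len(rise_len) / rise_len)))
  x <- x + rnorm(length(x), 0, 0.003)
  list(x = x, t_end = 1L, p_peak = length(x))
}
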