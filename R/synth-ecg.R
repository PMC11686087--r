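# Synthetic 12-lead ECG generator with analytically known fiducials.
#
# The P, QRS and T deflections are parametric pulses placed on a regular beat
# schedule, so the ground-truth onset/peak/offset of every P wave is known
# from the rendered template itself. Downstream delineation is tested against
# these truths.

# Fixed physiological cross-lead patterns (unitless multipliers). Cross-lead
# variation is required so amplitude and dispersion summaries are
# non-degenerate; aVR is inverted as in real recordings.
P_AMP_PATTERN <- c(I = 0.7, II = 1.0, III = 0.5, aVR = -0.9, aVL = 0.4,
                   aVF = 0.8, V1 = 1.0, V2 = 0.6, V3 = 0.7, V4 = 0.8,
                   V5 = 0.9, V6 = 0.7)
P_DUR_OFFSET_MS <- c(I = 0, II = 4, III = -4, aVR = -2, aVL = -6, aVF = 2,
                     V1 = 0, V2 = -2, V3 = 2, V4 = 4, V5 = 6, V6 = -4)
QRS_PATTERN <- c(I = 0.9, II = 1.0, III = 0.6, aVR = -0.9, aVL = 0.5,
                 aVF = 0.8, V1 = -0.8, V2 = -1.0, V3 = 0.9, V4 = 1.1,
                 V5 = 1.0, V6 = 0.9)
T_PATTERN <- c(I = 0.8, II = 1.0, III = 0.5, aVR = -0.8, aVL = 0.4,
               aVF = 0.8, V1 = 0.5, V2 = 0.9, V3 = 1.0, V4 = 0.9,
               V5 = 0.8, V6 = 0.7)

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Unimodal tapered-cosine pulse of n samples, peak 1 at the centre.
# `taper` is the per-side cosine-ramp fraction of the duration; the plateau
# carries a shallow cosine dome so the maximum is unique. The taper keeps
# the terminal deflection concentrated (so threshold-based offset detection
# agrees with the pulse support) while the 15% ramps stay below the 50 Hz
# pass-band edge of the pre-processing filter, which would otherwise smear
# the wave feet and bias duration measurement.
taper_pulse <- function(n, taper = 0.15, dome = 0.15) {
  if (n < 3) return(rep(1, n))
  u <- (seq_len(n) - 0.5) / n
  base <- rep(1, n)
  lo <- u < taper
  hi <- u > 1 - taper
  base[lo] <- 0.5 * (1 - cos(pi * u[lo] / taper))
  base[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / taper))
  w <- base * ((1 - dome) + dome * sin(pi * u))
  w / max(w)
}

#' Specification for one synthetic 12-lead ECG
#'
#' Defines heart rate, duration, sampling rate, per-lead P-wave duration and
#' amplitude (a scalar is scaled by a fixed physiological cross-lead
#' pattern), a biphasic P in V1, QRS/T amplitudes and noise terms.
#'
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param duration_s record duration, seconds.
#' @param sampling_rate_hz sampling rate, Hz (>= 250).
#' @param p_duration_ms P-wave onset-to-offset duration. Either a scalar
#'   (per-lead durations are the scalar plus a fixed small lead-to-lead
#'   offset pattern) or a named vector of 12 per-lead durations. Use
#'   `p_duration_uniform = TRUE` to force identical durations in all leads.
#' @param p_duration_uniform logical; if `TRUE` all leads use exactly
#'   `p_duration_ms` (scalar), giving zero true dispersion.
#' @param p_amplitude_mV P amplitude scale in mV; per-lead amplitude is this
#'   value times the fixed cross-lead pattern (aVR negative), or a named
#'   12-vector of per-lead signed amplitudes.
#' @param v1_biphasic_fraction fraction of the V1 P duration occupied by the
#'   terminal negative phase (0 gives a monophasic positive P in V1).
#' @param qrs_amplitude_mV,t_amplitude_mV QRS and T amplitude scales, mV.
#' @param noise_sd_mV additive white-noise SD, mV (>= 0).
#' @param baseline_wander_amplitude_mV amplitude of a 0.25 Hz sinusoidal
#'   baseline wander, mV.
#' @param seed integer RNG seed; identical specs give byte-identical output.
#' @return a `synth_ecg_spec` list.
#' @export
synth_ecg_spec <- function(heart_rate_bpm = 60, duration_s = 30,
                           sampling_rate_hz = 500, p_duration_ms = 120,
                           p_duration_uniform = FALSE,
                           p_amplitude_mV = 0.15,
                           v1_biphasic_fraction = 0.4,
                           qrs_amplitude_mV = 1.2, t_amplitude_mV = 0.22,
                           noise_sd_mV = 0.01,
                           baseline_wander_amplitude_mV = 0.05,
                           seed = 1L) {
  chk <- function(ok, field, why) if (!ok) stop(sprintf("invalid `%s`: %s", field, why))
  chk(is.numeric(heart_rate_bpm) && heart_rate_bpm > 20 && heart_rate_bpm < 250,
      "heart_rate_bpm", "must be in (20, 250)")
  chk(is.numeric(duration_s) && duration_s >= 3, "duration_s", "must be >= 3 s")
  chk(is.numeric(sampling_rate_hz) && sampling_rate_hz >= 250,
      "sampling_rate_hz", "must be >= 250 Hz")
  if (length(p_duration_ms) == 1) {
    dur <- if (isTRUE(p_duration_uniform)) {
      stats::setNames(rep(p_duration_ms, 12), ECG_LEADS)
    } else stats::setNames(p_duration_ms + P_DUR_OFFSET_MS[ECG_LEADS], ECG_LEADS)
  } else {
    chk(length(p_duration_ms) == 12 && all(ECG_LEADS %in% names(p_duration_ms)),
        "p_duration_ms", "per-lead vector must name all 12 leads")
    dur <- p_duration_ms[ECG_LEADS]
  }
  chk(all(dur > 20), "p_duration_ms", "all per-lead durations must exceed 20 ms")
  rr_ms <- 60000 / heart_rate_bpm
  chk(max(dur) < rr_ms * 0.35, "p_duration_ms",
      "P duration must fit inside the PR window implied by the heart rate")
  if (length(p_amplitude_mV) == 1) {
    amp <- stats::setNames(p_amplitude_mV * P_AMP_PATTERN[ECG_LEADS], ECG_LEADS)
  } else {
    chk(length(p_amplitude_mV) == 12 && all(ECG_LEADS %in% names(p_amplitude_mV)),
        "p_amplitude_mV", "per-lead vector must name all 12 leads")
    amp <- p_amplitude_mV[ECG_LEADS]
  }
  chk(is.numeric(v1_biphasic_fraction) && v1_biphasic_fraction >= 0 &&
        v1_biphasic_fraction < 0.6,
      "v1_biphasic_fraction", "must be in [0, 0.6)")
  chk(is.numeric(noise_sd_mV) && noise_sd_mV >= 0, "noise_sd_mV", "must be >= 0")
  chk(is.numeric(baseline_wander_amplitude_mV) && baseline_wander_amplitude_mV >= 0,
      "baseline_wander_amplitude_mV", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a single integer")
  structure(list(
    heart_rate_bpm = heart_rate_bpm, duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz, p_duration_ms = dur,
    p_amplitude_mV = amp, v1_biphasic_fraction = v1_biphasic_fraction,
    qrs_amplitude_mV = qrs_amplitude_mV, t_amplitude_mV = t_amplitude_mV,
    noise_sd_mV = noise_sd_mV,
    baseline_wander_amplitude_mV = baseline_wander_amplitude_mV,
    seed = as.integer(seed)), class = "synth_ecg_spec")
}

# P-wave lobe template: a half-raised-cosine rise over `rise` of the
# duration (spectrally inside the 1-50 Hz pass band, so the foot - and with
# it the chord-rule onset - survives pre-processing essentially unchanged,
# while staying short enough that the knee of the chord rule sits at the
# foot even for short T-end-to-peak windows) joined by a domed plateau to a
# concentrated cosine fall over `fall` of the duration (so the
# baseline-return offset rule lands at the template support). Peak 1,
# unique, near the centre.
p_shape <- function(n, rise = 0.3, fall = 0.15, dome = 0.15) {
  if (n < 3) return(rep(1, n))
  u <- (seq_len(n) - 0.5) / n
  base <- rep(1, n)
  lo <- u < rise
  hi <- u > 1 - fall
  base[lo] <- 0.5 * (1 - cos(pi * u[lo] / rise))
  base[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / fall))
  w <- base * ((1 - dome) + dome * sin(pi * u))
  w / max(w)
}

# Terminal-fall fraction: a fixed ~12 ms fall regardless of P duration
# (capped at 15% of the duration for short waves), so the offset-threshold
# bias does not scale with duration.
fall_frac <- function(n_samp, fs) min(0.15, (0.012 * fs) / n_samp)

# Render one P wave into x starting at sample `onset_i`; returns truth list.
render_p <- function(x, onset_i, n_samp, amp, biphasic_fraction, fs) {
  if (biphasic_fraction > 0) {
    n_neg <- round(biphasic_fraction * n_samp)
    n_pos <- n_samp - n_neg
    # the negative lobe rises quickly out of the positive lobe (atrial
    # activation is continuous across the phase change) and keeps the
    # concentrated terminal fall that defines the P offset
    w <- c(amp * p_shape(n_pos, fall = fall_frac(n_pos, fs)),
           -0.8 * amp * p_shape(n_neg, fall = fall_frac(n_neg, fs)))
  } else {
    w <- amp * p_shape(n_samp, fall = fall_frac(n_samp, fs))
  }
  idx <- onset_i:(onset_i + length(w) - 1L)
  x[idx] <- x[idx] + w
  nz <- which(abs(w) > 1e-12)
  neg <- which(w < -1e-12)
  list(x = x,
       onset = onset_i + nz[1] - 1L,
       peak = onset_i + which.max(abs(w)) - 1L,
       offset = onset_i + nz[length(nz)] - 1L,
       amp_mV = w[which.max(abs(w))],
       neg_duration_ms = length(neg) / fs * 1000,
       neg_peak_mV = if (length(neg)) min(w) else 0)
}

#' Generate a synthetic 12-lead ECG with ground-truth fiducials
#'
#' Places QRS complexes on a regular schedule at the requested heart rate,
#' follows each with a T wave (support scaled to the RR interval) and
#' precedes each with a P wave ending 90 ms before the QRS centre. Per-lead
#' white noise and sinusoidal baseline wander are added after the
#' ground-truth fiducials are read off the clean templates, so the truths
#' refer to the underlying waveform.
#'
#' @param spec a [synth_ecg_spec()].
#' @return list with `record` (an [ecg_record()]) and `fiducials`, a data
#'   frame with one row per rendered P wave per lead: `lead`, `beat`,
#'   `r` (QRS-centre sample), `t_end`, `p_onset`, `p_peak`, `p_offset`
#'   (sample indices), `p_amp_mV`, `neg_duration_ms`, `neg_peak_mV`.
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_ecg_spec"))
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  rr_s <- 60 / spec$heart_rate_bpm
  beat_t <- seq(0, spec$duration_s - 0.55 * rr_s, by = rr_s)
  if (length(beat_t) < 3) stop("record too short for the requested heart rate")
  sig <- matrix(0, nrow = n, ncol = 12, dimnames = list(NULL, ECG_LEADS))
  tt <- (seq_len(n) - 1) / fs

  # QRS: Ricker (Mexican-hat) wavelet, a qRs morphology with a dominant R
  # lobe flanked by Q and S deflections. Its net area is zero, so the
  # 1 Hz high-pass of the pre-processing stage leaves the isoelectric
  # baseline around the P wave essentially undistorted.
  qrs_rel <- seq(-round(0.04 * fs), round(0.04 * fs))
  tq <- qrs_rel / fs
  qrs_shape <- (1 - (tq / 0.014) ^ 2) * exp(-(tq ^ 2) / (2 * 0.014 ^ 2))

  fid <- vector("list", 12L)
  for (li in seq_along(ECG_LEADS)) {
    lead <- ECG_LEADS[li]
    x <- numeric(n)
    d_ms <- spec$p_duration_ms[[lead]]
    n_p <- round(d_ms / 1000 * fs)
    bi <- if (lead == "V1") spec$v1_biphasic_fraction else 0
    t_len <- round(0.16 * rr_s * fs)
    rows <- list()
    for (k in seq_along(beat_t)) {
      ri <- round(beat_t[k] * fs) + 1L
      # QRS
      qi <- ri + qrs_rel
      keep <- qi >= 1L & qi <= n
      x[qi[keep]] <- x[qi[keep]] +
        spec$qrs_amplitude_mV * QRS_PATTERN[[lead]] * qrs_shape[keep]
      # T wave: support [r + 0.22 RR, r + 0.42 RR]
      ti <- ri + round(0.22 * rr_s * fs)
      if (ti + t_len - 1L <= n) {
        tw <- spec$t_amplitude_mV * T_PATTERN[[lead]] * taper_pulse(t_len)
        x[ti:(ti + t_len - 1L)] <- x[ti:(ti + t_len - 1L)] + tw
        t_end_i <- ti + max(which(abs(tw) > 1e-12)) - 1L
      } else t_end_i <- NA_integer_
      # P wave preceding beat k (k >= 2): offset 90 ms before QRS centre
      if (k >= 2) {
        p_on <- ri - round(0.09 * fs) - n_p
        pr <- render_p(x, p_on, n_p, spec$p_amplitude_mV[[lead]], bi, fs)
        x <- pr$x
        rows[[length(rows) + 1L]] <- data.frame(
          lead = lead, beat = k - 1L, r = ri,
          t_end = NA_integer_,  # filled below from the preceding beat's T
          p_onset = pr$onset, p_peak = pr$peak, p_offset = pr$offset,
          p_amp_mV = pr$amp_mV, neg_duration_ms = pr$neg_duration_ms,
          neg_peak_mV = pr$neg_peak_mV, stringsAsFactors = FALSE)
      }
      if (k >= 2 && length(rows)) rows[[length(rows)]]$t_end <- prev_t_end
      prev_t_end <- t_end_i
    }
    df <- do.call(rbind, rows)
    sig[, lead] <- x
    fid[[li]] <- df
  }
  fiducials <- do.call(rbind, fid)
  rownames(fiducials) <- NULL

  with_seed(spec$seed, {
    for (lead in ECG_LEADS) {
      wander <- spec$baseline_wander_amplitude_mV *
        sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
      noise <- if (spec$noise_sd_mV > 0) stats::rnorm(n, 0, spec$noise_sd_mV) else 0
      sig[, lead] <- sig[, lead] + wander + noise
    }
  })
  list(record = ecg_record(sig, fs, sprintf("synth-hr%g-seed%d",
                                            spec$heart_rate_bpm, spec$seed)),
       fiducials = fiducials)
}
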