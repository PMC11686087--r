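# P-wave delineation.
#
# Per lead and per RR interval: estimate the isoelectric baseline from the
# TP segment, detect the P peak as the widest-supported largest excursion in
# the window between the preceding T-wave end and the next QRS onset (an
# excursion must hold at least 15 ms above half its height to count), locate
# the onset by the chord-distance rule between the T end and the P peak, and
# the offset by return to within 10% of the P amplitude of baseline. Twenty
# consecutive measurable beats are then averaged per lead.

#' Delineation configuration
#'
#' @param min_p_width_ms minimum excursion width for a P-peak candidate
#'   (measured at half the candidate height), default 15 ms.
#' @param n_beats number of consecutive measurable beats averaged per lead,
#'   default 20.
#' @param onset_rule `"chord_max_distance"` (default; the trapezium/knee
#'   rule: the sample between the T end and the P peak farthest from the
#'   chord joining them) or `"chord_min_distance_literal"` (the sample
#'   nearest the chord, endpoints excluded; degenerate in general and kept
#'   only for comparison).
#' @param offset_rule `"baseline_return"` (default: first sample after the
#'   peak staying within 10% of the P amplitude of baseline for >= 10 ms)
#'   or `"mirrored_chord"` (the chord rule applied between the P peak and
#'   the next QRS onset).
#' @param baseline_estimator `"pr_segment_mean"` (default: mean over the PR
#'   segment 85-45 ms before the next R peak, adjacent to the P offset where
#'   the baseline-return rule is evaluated) or `"tp_segment_median"` (median
#'   over the 10-60 ms after the T end).
#' @param qrs_guard_ms gap assumed between P search window end and the next
#'   R peak (QRS onset proxy), default 40 ms.
#' @param refractory_ms R-peak detection refractory period, default 200 ms.
#' @return a `delineation_config` list.
#' @export
delineation_config <- function(min_p_width_ms = 15, n_beats = 20,
                               onset_rule = c("chord_max_distance",
                                              "chord_min_distance_literal"),
                               offset_rule = c("baseline_return",
                                               "mirrored_chord"),
                               baseline_estimator = c("pr_segment_mean",
                                                      "tp_segment_median"),
                               qrs_guard_ms = 40, refractory_ms = 200) {
  stopifnot(min_p_width_ms > 0, n_beats >= 1)
  structure(list(min_p_width_ms = min_p_width_ms, n_beats = n_beats,
                 onset_rule = match.arg(onset_rule),
                 offset_rule = match.arg(offset_rule),
                 baseline_estimator = match.arg(baseline_estimator),
                 qrs_guard_ms = qrs_guard_ms, refractory_ms = refractory_ms),
            class = "delineation_config")
}

#' Detect R peaks on every lead
#'
#' Amplitude-threshold detector: candidate samples deviate from the lead
#' median by at least half the maximum deviation; candidates are accepted
#' greedily by height subject to a refractory period.
#'
#' @param record a pre-processed [ecg_record()].
#' @param refractory_ms minimum R-R separation, default 200 ms.
#' @return named list of integer R-peak index vectors, one per lead.
#' @export
detect_beats <- function(record, refractory_ms = 200) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate_hz
  refr <- round(refractory_ms / 1000 * fs)
  out <- lapply(ECG_LEADS, function(lead) {
    x <- record$samples[, lead]
    dev <- abs(x - stats::median(x))
    mx <- max(dev)
    if (mx <= 0) stop("flat signal in lead ", lead, ": no beats detectable")
    cand <- which(dev >= 0.5 * mx)
    ord <- cand[order(dev[cand], decreasing = TRUE)]
    acc <- integer(0)
    for (i in ord) if (!length(acc) || all(abs(acc - i) >= refr)) acc <- c(acc, i)
    acc <- sort(acc)
    if (length(acc) < 2)
      stop("fewer than 2 beats detected in lead ", lead)
    acc
  })
  names(out) <- ECG_LEADS
  out
}

#' Heart rate from the mean RR interval
#' @param rpeaks integer vector of R-peak sample indices.
#' @param fs sampling rate, Hz.
#' @return heart rate in beats per minute.
#' @export
heart_rate_bpm <- function(rpeaks, fs) {
  if (length(rpeaks) < 2) stop("need at least 2 R peaks for a heart rate")
  60 / (mean(diff(rpeaks)) / fs)
}

#' Estimate the isoelectric baseline over a window
#'
#' @param x numeric signal vector (one lead), mV.
#' @param window integer indices of the window used for the estimate.
#' @param estimator `"pr_segment_mean"` (mean; the default window used by
#'   [delineate_record()] sits on the PR segment) or `"tp_segment_median"`
#'   (median; robust to residual wave tails).
#' @return baseline level in mV.
#' @export
estimate_baseline <- function(x, window,
                              estimator = c("pr_segment_mean",
                                            "tp_segment_median")) {
  estimator <- match.arg(estimator)
  window <- window[window >= 1 & window <= length(x)]
  if (length(window) == 0) stop("empty baseline window")
  if (estimator == "tp_segment_median") stats::median(x[window])
  else mean(x[window])
}

# T-wave end by the tangent method: steepest slope on the limb of the T wave
# returning to baseline, extrapolated to the baseline crossing.
detect_t_end <- function(x, fs, r_i, r_next, baseline) {
  rr <- r_next - r_i
  w0 <- r_i + round(0.15 * rr)
  w1 <- r_i + round(0.55 * rr)
  w1 <- min(w1, length(x) - 1L, r_next - 1L)
  if (w1 - w0 < 4) return(NA_integer_)
  win <- w0:w1
  tpk <- win[which.max(abs(x[win] - baseline))]
  s0 <- tpk
  s1 <- min(tpk + round(0.20 * rr), length(x) - 1L, r_next - 1L)
  if (s1 - s0 < 2) return(NA_integer_)
  sl <- diff(x[s0:s1])
  j <- if (x[tpk] >= baseline) s0 + which.min(sl) - 1L else s0 + which.max(sl) - 1L
  slope <- x[j + 1L] - x[j]
  if (abs(slope) < 1e-12) return(NA_integer_)
  k <- (baseline - x[j]) / slope
  t_end <- as.integer(round(j + max(0, k)))
  min(max(t_end, tpk + 1L), r_next - 1L)
}

#' Detect the P-wave peak in a search window
#'
#' The peak is the sample with the largest vertical distance from the
#' isoelectric baseline among candidate excursions whose width at half the
#' candidate height is at least `min_width_ms`; narrower excursions (noise
#' spikes) are ignored. Returns `NA` when no sufficiently wide excursion
#' exists, in which case the beat is flagged unmeasurable.
#'
#' @param x numeric signal vector, mV.
#' @param window integer indices of the search window (T end to next QRS
#'   onset).
#' @param baseline isoelectric level, mV.
#' @param fs sampling rate, Hz.
#' @param min_width_ms minimum excursion width, default 15.
#' @return integer sample index of the P peak, or `NA_integer_`.
#' @export
detect_p_peak <- function(x, window, baseline, fs, min_width_ms = 15) {
  window <- window[window >= 1 & window <= length(x)]
  if (length(window) < 3) return(NA_integer_)
  dev <- abs(x[window] - baseline)
  n <- length(dev)
  is_max <- c(FALSE, dev[2:(n - 1)] >= dev[1:(n - 2)] &
                dev[2:(n - 1)] > dev[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(NA_integer_)
  min_w <- min_width_ms / 1000 * fs
  cand <- cand[order(dev[cand], decreasing = TRUE)]
  for (i in cand) {
    half <- dev[i] / 2
    if (half <= 0) next
    l <- i; while (l > 1 && dev[l - 1] >= half) l <- l - 1
    r <- i; while (r < n && dev[r + 1] >= half) r <- r + 1
    if ((r - l + 1) >= min_w) return(window[i])
  }
  NA_integer_
}

# Perpendicular distance from each sample (j, x[j]) to the chord joining
# (i1, x[i1]) and (i2, x[i2]), with the sample axis in index units.
chord_distance <- function(x, idx, i1, i2) {
  dx <- i2 - i1
  dy <- x[i2] - x[i1]
  len <- sqrt(dx * dx + dy * dy)
  if (len < 1e-12) return(rep(0, length(idx)))
  abs(dy * (idx - i1) - dx * (x[idx] - x[i1])) / len
}

#' Detect the P-wave onset by the chord rule
#'
#' The chord joins the T-wave end and the P-wave peak. Under the default
#' `chord_max_distance` rule the onset is the sample between them with the
#' maximum perpendicular distance to the chord (the knee of the waveform;
#' ties break to the earlier sample, the first point of rise above the
#' isoelectric line). The `chord_min_distance_literal` variant returns the
#' minimum-distance sample with the chord endpoints excluded.
#'
#' @param x numeric signal vector, mV.
#' @param t_end_index,p_peak_index chord anchor sample indices,
#'   `t_end_index < p_peak_index`.
#' @param rule onset rule, see above.
#' @return integer onset index, or `NA_integer_` when the chord is
#'   degenerate (all distances zero, e.g. a linear ramp).
#' @export
detect_p_onset <- function(x, t_end_index, p_peak_index,
                           rule = c("chord_max_distance",
                                    "chord_min_distance_literal")) {
  rule <- match.arg(rule)
  if (!(t_end_index < p_peak_index)) stop("T end must precede the P peak")
  if (t_end_index + 1L > p_peak_index - 1L) return(NA_integer_)
  idx <- seq(t_end_index + 1L, p_peak_index - 1L)
  d <- chord_distance(x, idx, t_end_index, p_peak_index)
  if (max(d) < 1e-9) return(NA_integer_)
  if (rule == "chord_max_distance") idx[which.max(d)] else idx[which.min(d)]
}

#' Detect the P-wave offset
#'
#' Default `baseline_return` rule: the first sample after the peak at which
#' the signal comes within 10% of the P amplitude of the baseline and stays
#' there for at least 10 ms (the persistence requirement makes the rule skip
#' the zero crossing inside a biphasic P, so the offset is the end of the
#' terminal phase). If the signal never returns before the next QRS onset
#' the offset is clamped there and flagged. The `mirrored_chord` variant
#' applies the chord rule between the P peak and the QRS onset.
#'
#' @param x numeric signal vector, mV.
#' @param p_peak_index P-peak sample index.
#' @param next_qrs_onset last admissible offset sample (QRS onset proxy).
#' @param baseline isoelectric level, mV.
#' @param fs sampling rate, Hz.
#' @param rule offset rule, see above.
#' @param return_fraction baseline-return threshold as a fraction of the P
#'   amplitude, default 0.1.
#' @param hold_ms persistence below threshold required, default 10 ms.
#' @return list with `index` (integer) and `clamped` (logical).
#' @export
detect_p_offset <- function(x, p_peak_index, next_qrs_onset, baseline, fs,
                            rule = c("baseline_return", "mirrored_chord"),
                            return_fraction = 0.1, hold_ms = 10) {
  rule <- match.arg(rule)
  if (!(p_peak_index < next_qrs_onset)) stop("P peak must precede QRS onset")
  if (rule == "mirrored_chord") {
    if (p_peak_index + 1L > next_qrs_onset - 1L)
      return(list(index = as.integer(next_qrs_onset), clamped = TRUE))
    idx <- seq(p_peak_index + 1L, next_qrs_onset - 1L)
    d <- chord_distance(x, idx, p_peak_index, next_qrs_onset)
    if (max(d) < 1e-9)
      return(list(index = as.integer(next_qrs_onset), clamped = TRUE))
    return(list(index = idx[which.max(d)], clamped = FALSE))
  }
  amp <- abs(x[p_peak_index] - baseline)
  thr <- return_fraction * amp
  h <- max(1L, round(hold_ms / 1000 * fs))
  idx <- seq(p_peak_index + 1L, next_qrs_onset)
  below <- abs(x[idx] - baseline) < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= h | ends == length(idx))
  if (any(ok))
    return(list(index = idx[starts[which(ok)[1]]], clamped = FALSE))
  list(index = as.integer(next_qrs_onset), clamped = TRUE)
}

# Measure the terminal negative phase of the P wave (used for PTFV1 in V1):
# the deepest contiguous run after the peak, within the P support, in which
# the signal lies more than 10% of the P amplitude on the far side of
# baseline from the peak.
measure_negative_phase <- function(x, p_peak_index, p_offset_index, baseline,
                                   fs, depth_fraction = 0.1) {
  if (p_offset_index <= p_peak_index + 1L)
    return(list(duration_ms = 0, peak_mV = 0))
  amp <- x[p_peak_index] - baseline
  idx <- seq(p_peak_index + 1L, p_offset_index)
  dev <- (x[idx] - baseline) * sign(amp)  # opposite phase is negative here
  opp <- dev < -depth_fraction * abs(amp)
  if (!any(opp)) return(list(duration_ms = 0, peak_mV = 0))
  r <- rle(opp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  depth <- vapply(runs, function(k) min(dev[starts[k]:ends[k]]), 0)
  k <- runs[which.min(depth)]
  seg <- idx[starts[k]:ends[k]]
  list(duration_ms = length(seg) / fs * 1000,
       peak_mV = min((x[seg] - baseline) * sign(amp)) * sign(amp))
}

# Delineate every RR interval of one lead. Returns a per-beat data frame.
delineate_lead <- function(x, fs, rpeaks, lead, config) {
  n_int <- length(rpeaks) - 1L
  rows <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    r_i <- rpeaks[i]; r_n <- rpeaks[i + 1L]
    row <- data.frame(lead = lead, beat = i, r = r_i, next_r = r_n,
                      t_end = NA_integer_, baseline_mV = NA_real_,
                      p_onset = NA_integer_, p_peak = NA_integer_,
                      p_offset = NA_integer_, pwd_ms = NA_real_,
                      pwa_mV = NA_real_, neg_duration_ms = NA_real_,
                      neg_peak_mV = NA_real_, measurable = FALSE,
                      clamped = FALSE, stringsAsFactors = FALSE)
    # the PR segment just before the next QRS is isoelectric by
    # construction of the cardiac cycle; it anchors the tangent baseline
    # robustly even at high heart rates where waves fill most of the RR
    pr0 <- max(r_i + 1L, r_n - round(0.085 * fs))
    pr1 <- max(pr0 + 1L, r_n - round(0.045 * fs))
    rough_base <- mean(x[pr0:pr1])
    t_end <- detect_t_end(x, fs, r_i, r_n, rough_base)
    if (is.na(t_end)) { rows[[i]] <- row; next }
    row$t_end <- t_end
    qrs_on <- r_n - round(config$qrs_guard_ms / 1000 * fs)
    if (qrs_on - t_end < 5) { rows[[i]] <- row; next }
    if (config$baseline_estimator == "tp_segment_median") {
      b0 <- t_end + round(0.01 * fs)
      b1 <- min(t_end + round(0.06 * fs), r_n - round(0.10 * fs))
    } else {
      b0 <- max(t_end + 1L, r_n - round(0.085 * fs))
      b1 <- r_n - round(0.045 * fs)
    }
    bw <- if (b1 >= b0 + 2) seq(b0, b1) else seq(t_end + 1L, qrs_on)
    base <- estimate_baseline(x, bw, config$baseline_estimator)
    row$baseline_mV <- base
    win <- seq(t_end + 1L, qrs_on)
    pk <- detect_p_peak(x, win, base, fs, config$min_p_width_ms)
    if (is.na(pk)) { rows[[i]] <- row; next }
    row$p_peak <- pk
    on <- detect_p_onset(x, t_end, pk, config$onset_rule)
    if (is.na(on)) { rows[[i]] <- row; next }
    off <- detect_p_offset(x, pk, qrs_on, base, fs, config$offset_rule)
    row$p_onset <- on
    row$p_offset <- off$index
    row$clamped <- off$clamped
    row$pwd_ms <- (off$index - on) / fs * 1000
    row$pwa_mV <- x[pk] - base
    np <- measure_negative_phase(x, pk, off$index, base, fs)
    row$neg_duration_ms <- np$duration_ms
    row$neg_peak_mV <- np$peak_mV
    row$measurable <- TRUE
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Delineate the P wave on every beat of every lead
#'
#' @param record a pre-processed [ecg_record()].
#' @param config a [delineation_config()].
#' @param rpeaks optional pre-computed result of [detect_beats()].
#' @param overrides optional manual-adjustment table with columns `lead`,
#'   `beat`, `field` (one of `p_onset`, `p_peak`, `p_offset`) and `index`;
#'   matching fiducials are replaced and the per-beat duration/amplitude
#'   recomputed.
#' @return data frame with one row per (lead, beat): fiducial sample
#'   indices, per-beat baseline, P duration (ms), signed P amplitude (mV),
#'   terminal negative-phase duration and peak, and a `measurable` flag.
#' @export
delineate_record <- function(record, config = delineation_config(),
                             rpeaks = NULL, overrides = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate_hz
  if (is.null(rpeaks)) rpeaks <- detect_beats(record, config$refractory_ms)
  out <- do.call(rbind, lapply(ECG_LEADS, function(lead)
    delineate_lead(record$samples[, lead], fs, rpeaks[[lead]], lead, config)))
  rownames(out) <- NULL
  if (!is.null(overrides)) out <- apply_fiducial_overrides(out, record, overrides)
  out
}

#' Apply manual fiducial adjustments
#'
#' Replaces the named fiducial indices and recomputes the derived per-beat
#' duration and amplitude. This is the programmatic equivalent of manual
#' adjustment during annotation.
#'
#' @param fiducials output of [delineate_record()].
#' @param record the [ecg_record()] the fiducials refer to.
#' @param overrides data frame with columns `lead`, `beat`, `field`, `index`.
#' @return the adjusted fiducial data frame.
#' @export
apply_fiducial_overrides <- function(fiducials, record, overrides) {
  stopifnot(all(c("lead", "beat", "field", "index") %in% names(overrides)))
  fs <- record$sampling_rate_hz
  for (k in seq_len(nrow(overrides))) {
    o <- overrides[k, ]
    j <- which(fiducials$lead == o$lead & fiducials$beat == o$beat)
    if (length(j) != 1) stop("override does not match a delineated beat: ",
                             o$lead, " beat ", o$beat)
    if (!o$field %in% c("p_onset", "p_peak", "p_offset"))
      stop("unknown override field: ", o$field)
    fiducials[j, o$field] <- as.integer(o$index)
    x <- record$samples[, o$lead]
    fiducials$pwd_ms[j] <-
      (fiducials$p_offset[j] - fiducials$p_onset[j]) / fs * 1000
    fiducials$pwa_mV[j] <- x[fiducials$p_peak[j]] - fiducials$baseline_mV[j]
    fiducials$measurable[j] <- fiducials$pwd_ms[j] > 0
  }
  fiducials
}

#' Average measurements over consecutive measurable beats
#'
#' Takes the first run of at least `n_beats` consecutive measurable beats
#' and returns the arithmetic mean of the per-beat measurements over the
#' first `n_beats` of that run, together with the number of beats used.
#'
#' @param beats per-beat data frame for one lead (rows of
#'   [delineate_record()] for a single lead).
#' @param n_beats number of consecutive beats to average, default 20.
#' @return list with `pwd_ms`, `pwa_mV`, `neg_duration_ms`, `neg_peak_mV`
#'   (means) and `n_beats_used`.
#' @export
average_measurements <- function(beats, n_beats = 20) {
  m <- beats$measurable
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n_beats)
  if (!length(ok)) {
    best <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    stop(sprintf(
      "need %d consecutive measurable beats but the longest run has %d",
      n_beats, best))
  }
  sel <- seq(starts[ok[1]], starts[ok[1]] + n_beats - 1L)
  b <- beats[sel, ]
  list(pwd_ms = mean(b$pwd_ms), pwa_mV = mean(b$pwa_mV),
       neg_duration_ms = mean(b$neg_duration_ms),
       neg_peak_mV = mean(b$neg_peak_mV), n_beats_used = length(sel))
}
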