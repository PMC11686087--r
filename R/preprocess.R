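# Pre-processing: mains notch plus 1-50 Hz band-pass, applied zero-phase.

#' Filter configuration for ECG pre-processing
#'
#' The measurement pipeline filters each lead with a mains notch filter and
#' a 1-50 Hz band-pass before delineation. The filter family and order are
#' implementation choices: 4th-order Butterworth band-pass and a 2nd-order
#' Butterworth band-stop notch, both run forward-backward (zero phase) so
#' that fiducial latencies, and hence P-wave durations, are not biased by
#' group delay.
#'
#' @param notch_freq_hz mains notch centre frequency (default 50 Hz;
#'   set 60 for 60 Hz mains, or `NA` to skip the notch).
#' @param bandpass_low_hz,bandpass_high_hz band-pass edges in Hz.
#' @param filter_order band-pass Butterworth order (the notch is 2nd order).
#' @param zero_phase apply filters forward-backward (default `TRUE`).
#' @param notch_halfwidth_hz half-width of the notch stop band, Hz.
#' @return a `filter_config` list.
#' @export
filter_config <- function(notch_freq_hz = 50, bandpass_low_hz = 1,
                          bandpass_high_hz = 50, filter_order = 4,
                          zero_phase = TRUE, notch_halfwidth_hz = 2) {
  if (!(bandpass_low_hz > 0 && bandpass_low_hz < bandpass_high_hz))
    stop("band-pass edges must satisfy 0 < low < high")
  structure(list(notch_freq_hz = notch_freq_hz,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 filter_order = filter_order, zero_phase = zero_phase,
                 notch_halfwidth_hz = notch_halfwidth_hz),
            class = "filter_config")
}

apply_filt <- function(x, filt, zero_phase) {
  if (zero_phase) signal::filtfilt(filt, x) else signal::filter(filt, x)
}

#' Apply the notch + band-pass pre-processing to a record
#'
#' @param record an [ecg_record()].
#' @param config a [filter_config()].
#' @return an [ecg_record()] of the same length with each lead filtered.
#' @export
preprocess <- function(record, config = filter_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "filter_config"))
  fs <- record$sampling_rate_hz
  nyq <- fs / 2
  if (config$bandpass_high_hz >= nyq)
    stop(sprintf("band-pass upper edge %g Hz infeasible at %g Hz sampling",
                 config$bandpass_high_hz, fs))
  bp <- signal::butter(config$filter_order,
                       c(config$bandpass_low_hz, config$bandpass_high_hz) / nyq,
                       type = "pass")
  notch <- NULL
  if (!is.na(config$notch_freq_hz)) {
    if (config$notch_freq_hz <= 0 || config$notch_freq_hz >= nyq)
      stop("notch frequency must lie in (0, Nyquist)")
    lo <- max(config$notch_freq_hz - config$notch_halfwidth_hz, 0.1)
    hi <- min(config$notch_freq_hz + config$notch_halfwidth_hz, nyq * 0.999)
    notch <- signal::butter(2, c(lo, hi) / nyq, type = "stop")
  }
  out <- record$samples
  for (lead in colnames(out)) {
    x <- out[, lead]
    if (!is.null(notch)) x <- apply_filt(x, notch, config$zero_phase)
    x <- apply_filt(x, bp, config$zero_phase)
    out[, lead] <- x
  }
  ecg_record(out, fs, record$source_id)
}
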