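#' Standard 12-lead names, in conventional order
#'
#' Limb leads I, II, III, augmented leads aVR, aVL, aVF, and precordial
#' leads V1-V6.
#'
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG record
#'
#' An `ecg_record` holds one multichannel digital ECG: a numeric matrix of
#' samples in millivolts (one column per lead), a common sampling rate, and
#' the canonical lead names. All leads must be the same length and the record
#' must span at least one second.
#'
#' @param samples numeric matrix, one column per lead, values in mV. Column
#'   names must be the 12 standard lead names (any order; columns are
#'   reordered canonically).
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param source_id free-text identifier carried through outputs.
#'
#' @return An object of class `ecg_record` with elements `samples`,
#'   `sampling_rate_hz`, `lead_names`, `source_id`.
#' @export
ecg_record <- function(samples, sampling_rate_hz, source_id = "") {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix with one column per lead")
  if (is.null(colnames(samples)))
    stop("`samples` must have lead names as column names")
  missing <- setdiff(ECG_LEADS, colnames(samples))
  if (length(missing) > 0)
    stop("missing leads: ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(samples), ECG_LEADS)
  if (length(extra) > 0)
    stop("unknown leads: ", paste(extra, collapse = ", "))
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a single positive number")
  if (nrow(samples) < sampling_rate_hz)
    stop("record must contain at least 1 s of samples")
  structure(
    list(samples = samples[, ECG_LEADS, drop = FALSE],
         sampling_rate_hz = sampling_rate_hz,
         lead_names = ECG_LEADS,
         source_id = as.character(source_id)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: 12 leads, %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Record duration in seconds
#' @param record an `ecg_record`.
#' @return duration in seconds.
#' @export
ecg_duration_s <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  nrow(record$samples) / record$sampling_rate_hz
}

#' Extract a time window from a record
#'
#' Returns the sub-record starting at `start_s` seconds and lasting
#' `length_s` seconds (default one minute, the per-stage analysis window
#' used around the ablation procedure).
#'
#' @param record an `ecg_record`.
#' @param start_s window start, seconds from the beginning of the record.
#' @param length_s window length in seconds (default 60).
#' @return an `ecg_record` containing exactly `length_s` seconds of samples.
#' @export
extract_window <- function(record, start_s = 0, length_s = 60) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate_hz
  if (start_s < 0 || length_s <= 0)
    stop("window start must be >= 0 and length > 0")
  i0 <- round(start_s * fs) + 1L
  n <- round(length_s * fs)
  if (i0 > nrow(record$samples))
    stop("window start beyond end of record")
  if (i0 + n - 1L > nrow(record$samples))
    stop(sprintf("window [%g, %g] s exceeds record duration %.3f s",
                 start_s, start_s + length_s, ecg_duration_s(record)))
  ecg_record(record$samples[i0:(i0 + n - 1L), , drop = FALSE],
             fs, record$source_id)
}
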