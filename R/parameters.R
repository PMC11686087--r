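# The four P-wave parameters: heart-rate-corrected duration (Hodges), peak
# amplitude, dispersion across the 12 leads, and terminal force in V1.

#' Hodges heart-rate correction of the P-wave duration
#'
#' PWDc = PWD + 1.75 x (HR - 60), the linear correction used for QT
#' intervals, applied here to the P-wave duration. At 60 bpm the corrected
#' and raw durations coincide.
#'
#' @param pwd_ms P-wave duration, ms (> 0).
#' @param heart_rate_bpm heart rate, beats per minute, in (20, 250).
#' @return corrected P-wave duration, ms.
#' @export
correct_pwd_hodges <- function(pwd_ms, heart_rate_bpm) {
  if (any(pwd_ms <= 0)) stop("`pwd_ms` must be positive")
  if (any(heart_rate_bpm <= 20 | heart_rate_bpm >= 250))
    stop("non-physiological heart rate: must be in (20, 250) bpm")
  pwd_ms + 1.75 * (heart_rate_bpm - 60)
}

#' Summarize per-lead P-wave durations into one value
#'
#' Default is the maximum across measurable leads (the P-max convention,
#' the natural companion of dispersion); `rule = "mean"` averages instead.
#'
#' @param pwd_ms numeric vector of per-lead durations, ms (NAs dropped).
#' @param rule `"max"` (default) or `"mean"`.
#' @return scalar duration, ms.
#' @export
summarize_pwd <- function(pwd_ms, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  pwd_ms <- pwd_ms[!is.na(pwd_ms)]
  if (!length(pwd_ms)) stop("no measurable leads")
  if (rule == "max") max(pwd_ms) else mean(pwd_ms)
}

#' Summarize per-lead P-wave amplitudes
#'
#' The amplitude is the vertical distance from the isoelectric line to the
#' P peak; per-lead values are signed relative to baseline and the summary
#' is the maximum magnitude across leads (mean available by `rule`).
#'
#' @param pwa_mV numeric vector of signed per-lead amplitudes, mV.
#' @param rule `"max_abs"` (default) or `"mean_abs"`.
#' @return scalar amplitude magnitude, mV.
#' @export
compute_pwa <- function(pwa_mV, rule = c("max_abs", "mean_abs")) {
  rule <- match.arg(rule)
  pwa_mV <- pwa_mV[!is.na(pwa_mV)]
  if (!length(pwa_mV)) stop("no measurable leads")
  if (rule == "max_abs") max(abs(pwa_mV)) else mean(abs(pwa_mV))
}

#' P-wave dispersion
#'
#' Maximum minus minimum P-wave duration across measurable leads.
#'
#' @param pwd_ms numeric vector of per-lead durations, ms.
#' @return dispersion in ms (>= 0).
#' @export
compute_pwdisp <- function(pwd_ms) {
  pwd_ms <- pwd_ms[!is.na(pwd_ms)]
  if (length(pwd_ms) < 2) stop("dispersion needs at least 2 measurable leads")
  max(pwd_ms) - min(pwd_ms)
}

#' P-wave terminal force in V1
#'
#' The product of the maximum absolute amplitude of the terminal negative
#' phase of the P wave in V1 (expressed in mm at the standard 0.1 mV/mm
#' calibration) and its duration in seconds; reported negative by
#' convention. Zero for a monophasic positive P.
#'
#' @param neg_peak_mV most negative terminal-phase amplitude relative to
#'   baseline, mV (<= 0; values >= 0 mean no negative phase).
#' @param neg_duration_ms terminal negative-phase duration, ms.
#' @param scale optional unit scale factor applied to the canonical
#'   mm.s value, default 1.
#' @return terminal force in mm.s (<= 0).
#' @export
compute_ptfv1 <- function(neg_peak_mV, neg_duration_ms, scale = 1) {
  if (is.na(neg_peak_mV) || is.na(neg_duration_ms)) stop("V1 measurement absent")
  if (neg_peak_mV >= 0 || neg_duration_ms <= 0) return(0)
  -(abs(neg_peak_mV) / 0.1) * (neg_duration_ms / 1000) * scale
}

#' Compute the full parameter set for one record stage
#'
#' Runs beat detection and delineation (unless supplied), averages the
#' configured number of consecutive measurable beats per lead, and
#' assembles: PWDc (per-lead durations summarized then Hodges-corrected at
#' the heart rate from the mean RR interval), PWA, PWDisp, and PTFV1 from
#' the V1 terminal negative phase.
#'
#' @param record a pre-processed [ecg_record()].
#' @param config a [delineation_config()].
#' @param stage `"pre"` or `"post"`, carried through to the output.
#' @param pwd_rule,pwa_rule per-lead summary conventions, see
#'   [summarize_pwd()] and [compute_pwa()].
#' @param ptfv1_scale unit scale for PTFV1, default 1 (mm.s).
#' @param fiducials optional pre-computed [delineate_record()] output.
#' @param overrides optional manual-adjustment table, see
#'   [apply_fiducial_overrides()].
#' @return an object of class `parameter_set`: `pwdc_ms`, `pwa_mV`,
#'   `pwdisp_ms`, `ptfv1_mms`, `heart_rate_bpm`, `stage`, `leads_used`, and
#'   `per_lead` (the averaged per-lead measurement table).
#' @export
compute_parameter_set <- function(record, config = delineation_config(),
                                  stage = c("pre", "post"),
                                  pwd_rule = "max", pwa_rule = "max_abs",
                                  ptfv1_scale = 1, fiducials = NULL,
                                  overrides = NULL) {
  stage <- match.arg(stage)
  fs <- record$sampling_rate_hz
  rpeaks <- detect_beats(record, config$refractory_ms)
  if (is.null(fiducials))
    fiducials <- delineate_record(record, config, rpeaks, overrides)
  per_lead <- do.call(rbind, lapply(ECG_LEADS, function(lead) {
    b <- fiducials[fiducials$lead == lead, , drop = FALSE]
    av <- tryCatch(average_measurements(b, config$n_beats), error = function(e) NULL)
    if (is.null(av))
      return(data.frame(lead = lead, pwd_ms = NA_real_, pwa_mV = NA_real_,
                        neg_duration_ms = NA_real_, neg_peak_mV = NA_real_,
                        n_beats_used = 0L, stringsAsFactors = FALSE))
    data.frame(lead = lead, pwd_ms = av$pwd_ms, pwa_mV = av$pwa_mV,
               neg_duration_ms = av$neg_duration_ms,
               neg_peak_mV = av$neg_peak_mV, n_beats_used = av$n_beats_used,
               stringsAsFactors = FALSE)
  }))
  usable <- !is.na(per_lead$pwd_ms)
  if (sum(usable) < 2)
    stop("fewer than 2 leads with ", config$n_beats,
         " consecutive measurable beats")
  hr <- heart_rate_bpm(rpeaks[["II"]], fs)
  pwd <- summarize_pwd(per_lead$pwd_ms, pwd_rule)
  v1 <- per_lead[per_lead$lead == "V1", ]
  ptf <- if (is.na(v1$pwd_ms)) NA_real_ else
    compute_ptfv1(v1$neg_peak_mV, v1$neg_duration_ms, ptfv1_scale)
  structure(list(
    pwdc_ms = correct_pwd_hodges(pwd, hr),
    pwa_mV = compute_pwa(per_lead$pwa_mV, pwa_rule),
    pwdisp_ms = compute_pwdisp(per_lead$pwd_ms),
    ptfv1_mms = ptf,
    heart_rate_bpm = hr, stage = stage,
    leads_used = sum(usable), per_lead = per_lead), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(paste0("<parameter_set> stage=%s leads=%d HR=%.1f bpm\n",
                     "  PWDc %.1f ms | PWA %.3f mV | PWDisp %.1f ms | ",
                     "PTFV1 %s mm.s\n"),
              x$stage, x$leads_used, x$heart_rate_bpm, x$pwdc_ms, x$pwa_mV,
              x$pwdisp_ms,
              if (is.na(x$ptfv1_mms)) "NA" else sprintf("%.3f", x$ptfv1_mms)))
  invisible(x)
}
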