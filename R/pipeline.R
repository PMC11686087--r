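# End-to-end orchestration: simulate a cohort, synthesize pre/post ECGs per
# patient, delineate, compute parameter sets, and run the cohort statistics,
# writing every stage's output plus a manifest into a run directory.

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output run directory (created; stages write to `raw/`,
#'   `fiducials/`, `parameters/`, `stats/`).
#' @param cohort_spec a [synth_cohort_spec()] describing the cohort.
#' @param filter_config a [filter_config()].
#' @param delineation_config a [delineation_config()].
#' @param ecg_sampling_rate_hz sampling rate of the synthesized ECGs.
#' @param ecg_duration_s per-stage ECG duration, seconds.
#' @param pwd_rule,pwa_rule,ptfv1_scale parameter conventions, see
#'   [compute_parameter_set()].
#' @param cox_threshold univariable screen threshold.
#' @param covariates covariate names for the Cox screen; defaults to the
#'   standardized parameter changes plus a set of null clinical covariates.
#' @param seed integer seed recorded in the manifest.
#' @param write_raw also write each synthesized ECG as CSV (slow; default
#'   `FALSE`).
#' @param keep_going continue past per-patient measurement failures,
#'   recording them in the manifest (default `FALSE`).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, cohort_spec = synth_cohort_spec(),
                       filter_config = pwavePVI::filter_config(),
                       delineation_config = pwavePVI::delineation_config(),
                       ecg_sampling_rate_hz = 500, ecg_duration_s = 30,
                       pwd_rule = "max", pwa_rule = "max_abs",
                       ptfv1_scale = 1, cox_threshold = 0.05,
                       covariates = c("z_pwdc_change", "z_pwa_change", "age",
                                      "male", "hypertension", "lvef",
                                      "potassium", "bmi"),
                       seed = 1L, write_raw = FALSE, keep_going = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

# Map a patient-stage parameter target onto an ECG spec. The cohort's PWDc
# values are taken at 60 bpm (so PWD = PWDc) and its display-unit amplitudes
# are mapped to waveform millivolts at 0.1 mV per display unit.
patient_stage_ecg_spec <- function(pwdc_ms, pwa, fs, duration_s, seed) {
  synth_ecg_spec(heart_rate_bpm = 60, duration_s = duration_s,
                 sampling_rate_hz = fs,
                 p_duration_ms = max(pwdc_ms, 60), p_duration_uniform = TRUE,
                 p_amplitude_mV = max(0.1 * pwa, 0.02),
                 seed = seed)
}

#' Run the full synthetic pipeline
#'
#' Generates the cohort, synthesizes a pre- and post-stage ECG per patient
#' whose P-wave duration and amplitude realize the patient's drawn
#' parameters, filters and delineates each ECG, computes the parameter
#' sets, and runs the cohort statistics (paired and between-group change
#' tests on the measured PWDc, and the Cox screen on the cohort table).
#' Every output file is listed in `manifest.json` with an MD5 checksum,
#' the seed and the configuration.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `parameters` (per patient-stage measured
#'   parameter table), `cohort`, `stats`, `manifest_path`, and `failures`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dirs <- file.path(config$out_dir,
                    c("raw", "fiducials", "parameters", "stats"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort_spec)
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  failures <- list()
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    for (stage in c("pre", "post")) {
      res <- tryCatch({
        spec <- patient_stage_ecg_spec(
          cohort[[paste0("pwdc_", stage)]][i],
          cohort[[paste0("pwa_", stage)]][i],
          config$ecg_sampling_rate_hz, config$ecg_duration_s,
          seed = config$seed * 1000L + i * 2L + (stage == "post"))
        gen <- generate_ecg(spec)
        rec <- preprocess(gen$record, config$filter_config)
        fids <- delineate_record(rec, config$delineation_config)
        write_fiducials_csv(
          cbind(id = cohort$id[i], stage = stage, fids),
          file.path(config$out_dir, "fiducials",
                    sprintf("%s_%s.csv", cohort$id[i], stage)))
        if (config$write_raw)
          write_ecg_csv(gen$record,
                        file.path(config$out_dir, "raw",
                                  sprintf("%s_%s.csv", cohort$id[i], stage)))
        ps <- compute_parameter_set(rec, config$delineation_config,
                                    stage = stage,
                                    pwd_rule = config$pwd_rule,
                                    pwa_rule = config$pwa_rule,
                                    ptfv1_scale = config$ptfv1_scale,
                                    fiducials = fids)
        data.frame(id = cohort$id[i], stage = stage, pwdc_ms = ps$pwdc_ms,
                   pwa_mV = ps$pwa_mV, pwdisp_ms = ps$pwdisp_ms,
                   ptfv1_mms = ps$ptfv1_mms,
                   heart_rate_bpm = ps$heart_rate_bpm,
                   leads_used = ps$leads_used, stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        msg <- sprintf("measurement failed for %s (%s): %s",
                       cohort$id[i], stage, conditionMessage(res))
        if (!config$keep_going) stop(msg)
        failures[[length(failures) + 1L]] <- msg
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  params <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), stage = character(0),
               pwdc_ms = numeric(0), pwa_mV = numeric(0),
               pwdisp_ms = numeric(0), ptfv1_mms = numeric(0),
               heart_rate_bpm = numeric(0), leads_used = integer(0))
  utils::write.csv(params,
                   file.path(config$out_dir, "parameters", "parameters.csv"),
                   row.names = FALSE)
  # cohort statistics on the measured PWDc values (need paired stages and
  # both outcome groups; otherwise the stage is skipped)
  paired <- between <- NULL
  stats_dir <- file.path(config$out_dir, "stats")
  if (nrow(params) > 0) {
    wide <- merge(params[params$stage == "pre", c("id", "pwdc_ms")],
                  params[params$stage == "post", c("id", "pwdc_ms")],
                  by = "id", suffixes = c("_pre", "_post"))
    wide <- merge(wide, cohort[, c("id", "group")], by = "id")
    if (nrow(wide) >= 3) {
      paired <- paired_change_test(wide$pwdc_ms_pre, wide$pwdc_ms_post)
      ch <- wide$pwdc_ms_post - wide$pwdc_ms_pre
      between <- tryCatch(
        between_group_change_test(ch[wide$group == "success"],
                                  ch[wide$group == "failure"]),
        error = function(e) NULL)
    }
  }
  cox <- tryCatch(
    cox_screen_and_fit(cohort, config$covariates, config$cox_threshold),
    error = function(e) e)
  if (!is.null(paired)) {
    utils::write.csv(
      data.frame(analysis = c("paired_pwdc", "between_group_pwdc"),
                 estimate = c(paired$mean_change,
                              if (is.null(between)) NA else between$difference),
                 p_value = c(paired$p_value,
                             if (is.null(between)) NA else between$p_value),
                 test = c(paired$test,
                          if (is.null(between)) NA else between$test)),
      file.path(stats_dir, "change_tests.csv"), row.names = FALSE)
  }
  if (!inherits(cox, "error"))
    utils::write.csv(cox, file.path(stats_dir, "cox_results.csv"),
                     row.names = FALSE)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_patients = nrow(cohort),
    failures = unlist(failures),
    config = config[setdiff(names(config),
                            c("cohort_spec", "filter_config",
                              "delineation_config"))],
    files = data.frame(path = sub(paste0("^", config$out_dir, "/?"), "",
                                  files),
                       md5 = unname(tools::md5sum(files))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(parameters = params, cohort = cohort,
                 stats = list(paired = paired, between = between, cox = cox),
                 manifest_path = manifest_path,
                 failures = unlist(failures)))
}
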