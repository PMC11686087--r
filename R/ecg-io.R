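# Reading and writing ECG records.
#
# Two dialects: (a) plain CSV, one column per lead with a header row of lead
# names, values in mV; (b) a minimal WFDB record (text .hea header plus a
# single format-16 .dat file of interleaved little-endian 16-bit ADC units),
# which covers the 16-bit / +-10 mV recordings the measurement pipeline was
# designed for. Gain and baseline are honoured on read for WFDB; CSV is
# assumed to be in mV already.

#' Read a 12-lead ECG record
#'
#' @param path file path: a `.csv` file, or a WFDB header path (`.hea`,
#'   or the record name without extension).
#' @param format `"csv"` or `"wfdb"`; inferred from the extension by default.
#' @param sampling_rate_hz required for CSV (the dialect carries no rate).
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"),
                     sampling_rate_hz = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  if (format == "csv") {
    if (is.null(sampling_rate_hz))
      stop("`sampling_rate_hz` is required when reading CSV")
    df <- utils::read.csv(path, check.names = FALSE)
    missing <- setdiff(ECG_LEADS, names(df))
    if (length(missing) > 0)
      stop("missing leads in ", path, ": ", paste(missing, collapse = ", "))
    m <- as.matrix(df[, ECG_LEADS, drop = FALSE])
    ecg_record(m, sampling_rate_hz, source_id = basename(path))
  } else {
    read_wfdb(path)
  }
}

#' Write a record as per-lead CSV (values in mV)
#' @param record an [ecg_record()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.csv(as.data.frame(record$samples), path, row.names = FALSE)
  invisible(path)
}

#' Write a record as a minimal WFDB record (format 16)
#'
#' Emits `<name>.hea` and `<name>.dat`. Samples are scaled by `gain` ADC
#' units per mV and stored as interleaved little-endian 16-bit integers,
#' i.e. the 16-bit resolution of the source recordings; values outside the
#' representable range are clipped.
#'
#' @param record an [ecg_record()].
#' @param path record path without extension (directory must exist).
#' @param gain ADC units per mV (default 3276.7, i.e. +-10 mV full scale).
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 3276.7) {
  stopifnot(inherits(record, "ecg_record"))
  name <- basename(path)
  n <- nrow(record$samples)
  adc <- round(record$samples * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  header <- c(
    sprintf("%s 12 %g %d", name, record$sampling_rate_hz, n),
    sprintf("%s.dat 16 %.4f(0)/mV 16 0 %d 0 0 %s",
            name, gain, adc[1, ], colnames(adc)))
  writeLines(header, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(paste0(path, ".hea"))
}

#' Read a minimal WFDB record (single format-16 signal file)
#' @param path header path (`.hea` optional).
#' @return an [ecg_record()] with samples converted to mV via the header gain.
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig_lines <- lines[seq_len(nsig) + 1L]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (f[2] != "16")
      stop("unsupported WFDB signal format: ", f[2], " (only format 16)")
    gain_spec <- f[3]
    if (!grepl("mV$", gain_spec) && grepl("/", gain_spec))
      stop("unknown units in WFDB gain field: ", gain_spec)
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    list(file = f[1], gain = gain, name = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  datf <- unique(vapply(sigs, `[[`, "", "file"))
  if (length(datf) != 1)
    stop("multi-file WFDB records are not supported")
  con <- file(file.path(dirname(hea), datf), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * nsamp, size = 2L,
                 endian = "little", signed = TRUE)
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig)) m[, j] <- m[, j] / sigs[[j]]$gain
  colnames(m) <- vapply(sigs, `[[`, "", "name")
  missing <- setdiff(ECG_LEADS, colnames(m))
  if (length(missing) > 0)
    stop("missing leads in ", hea, ": ", paste(missing, collapse = ", "))
  ecg_record(m, fs, source_id = sub("\\.hea$", "", basename(hea)))
}

#' Write a fiducial table as CSV
#'
#' One row per (record, lead, beat) with onset/peak/offset sample indices
#' and the per-beat baseline, the annotation interchange format used by the
#' delineation stage.
#'
#' @param fiducials data frame of fiducials (see [delineate_record()]).
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  utils::write.csv(fiducials, path, row.names = FALSE)
  invisible(path)
}
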