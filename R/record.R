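#' ECG records and corpora
#'
#' A *record* is one continuous annotated ECG trace from one patient. A
#' *corpus* is a tibble with one row per record and the signal and rhythm
#' annotations held in list-columns, so corpora compose with the usual dplyr
#' verbs. Amplitudes are in microvolts throughout.
#'
#' Recognised rhythm labels are `VF`, `VT`, `NSR`, `SVT`, `PEA`, `PR`, `AS`,
#' `NOISE` and `OTHER_NSH`. `VT` intervals may carry a `rate_bpm` (from the
#' source annotations); where absent, rates are estimated from detected peaks.
#'
#' @param patient_id patient identifier (coerced to character).
#' @param fs sampling rate in Hz (> 0).
#' @param samples numeric vector of ECG amplitudes in microvolts.
#' @param annotations tibble/data.frame with columns `start_s`, `end_s`,
#'   `rhythm` and optionally `rate_bpm`; intervals must be ordered,
#'   non-overlapping and inside the record extent.
#' @param record_id optional record identifier; defaults to the patient id.
#' @return a one-row corpus tibble with columns `patient_id`, `record_id`,
#'   `fs`, `samples` (list) and `annotations` (list).
#' @examples
#' rec <- ecg_record("p1", 250, sin(2 * pi * 5 * seq(0, 8, by = 1 / 250)),
#'   annotations = data.frame(start_s = 0, end_s = 8, rhythm = "VF")
#' )
#' @export
ecg_record <- function(patient_id, fs, samples, annotations,
                       record_id = NULL) {
  patient_id <- as.character(patient_id)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number", class = "shockable_error")
  }
  if (!is.numeric(samples) || length(samples) == 0) {
    abort("`samples` must be a non-empty numeric vector",
      class = "shockable_error"
    )
  }
  ann <- as_tibble(annotations)
  if (!all(c("start_s", "end_s", "rhythm") %in% names(ann))) {
    abort("annotations need columns start_s, end_s, rhythm",
      class = "shockable_error"
    )
  }
  if (!"rate_bpm" %in% names(ann)) ann$rate_bpm <- NA_real_
  ann <- ann[order(ann$start_s), c("start_s", "end_s", "rhythm", "rate_bpm")]
  ann$rhythm <- as.character(ann$rhythm)
  dur <- length(samples) / fs
  if (nrow(ann)) {
    if (any(ann$end_s <= ann$start_s)) {
      abort("annotation intervals must have end_s > start_s",
        class = "shockable_error"
      )
    }
    if (any(ann$start_s < -1e-9) || any(ann$end_s > dur + 1e-9)) {
      abort("annotations must lie within the record extent",
        class = "shockable_error"
      )
    }
    if (nrow(ann) > 1 &&
      any(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-9)) {
      abort("annotation intervals must not overlap", class = "shockable_error")
    }
  }
  tibble(
    patient_id = patient_id,
    record_id = as.character(record_id %||% patient_id),
    fs = fs,
    samples = list(as.numeric(samples)),
    annotations = list(ann)
  )
}

rhythm_labels <- c(
  "VF", "VT", "NSR", "SVT", "PEA", "PR", "AS", "NOISE", "OTHER_NSH"
)

#' Read and write records as CSV
#'
#' The CSV dialect stores one `(time_s, uv)` sample per row; annotations go
#' in a sidecar `<stem>.ann.csv` with columns `start_s`, `end_s`, `rhythm`,
#' `rate_bpm`. [write_record_csv()] creates both files; [read_record_csv()]
#' reconstructs the record (sampling rate is inferred from the time column).
#'
#' @param record a one-row corpus tibble (see [ecg_record()]).
#' @param path path of the signal CSV (the annotation path is derived).
#' @return `read_record_csv()` returns a one-row corpus tibble.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(nrow(record) == 1)
  x <- record$samples[[1]]
  readr::write_csv(
    tibble(
      time_s = (seq_along(x) - 1) / record$fs,
      uv = x
    ),
    path
  )
  readr::write_csv(record$annotations[[1]], ann_path(path))
  invisible(path)
}

#' @rdname write_record_csv
#' @param patient_id,record_id identifiers for the reconstructed record.
#' @export
read_record_csv <- function(path, patient_id, record_id = NULL) {
  sig <- readr::read_csv(path, show_col_types = FALSE)
  ann <- readr::read_csv(ann_path(path), show_col_types = FALSE)
  fs <- round(1 / median(diff(sig$time_s)))
  ecg_record(patient_id, fs, sig$uv, ann, record_id = record_id)
}

ann_path <- function(path) {
  sub("\\.csv$", ".ann.csv", path)
}

#' Minimal WFDB-compatible record io
#'
#' Writes/reads single-signal WFDB format-16 records (`.hea` header plus
#' 16-bit little-endian `.dat`), enough to interchange with PhysioNet
#' tooling for single-channel traces. Rhythm annotations are carried in a
#' plain-text sidecar `<record>.ann.txt` (`start_s end_s rhythm rate_bpm`
#' per line) rather than the binary `.atr` format, which is only needed for
#' the public-database reproduction workflow and is out of scope here.
#'
#' @param record a one-row corpus tibble.
#' @param dir directory for the record files.
#' @param name record name (file stem).
#' @param adc_gain ADC units per millivolt written to the header.
#' @return `read_record_wfdb()` returns a one-row corpus tibble.
#' @export
write_record_wfdb <- function(record, dir, name, adc_gain = 200) {
  stopifnot(nrow(record) == 1)
  x <- record$samples[[1]]
  # uv -> mV -> adc units
  adc <- as.integer(round(x / 1000 * adc_gain))
  adc <- pmax(pmin(adc, 32767L), -32768L)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- file.path(dir, paste0(name, ".dat"))
  writeLines(
    c(
      sprintf("%s 1 %g %d", name, record$fs, length(adc)),
      sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 ECG", name, adc_gain, adc[1]),
      sprintf("# patient_id %s", record$patient_id)
    ),
    hea
  )
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  ann <- record$annotations[[1]]
  writeLines(
    sprintf(
      "%.6f %.6f %s %s", ann$start_s, ann$end_s, ann$rhythm,
      ifelse(is.na(ann$rate_bpm), "NA", format(ann$rate_bpm))
    ),
    file.path(dir, paste0(name, ".ann.txt"))
  )
  invisible(hea)
}

#' @rdname write_record_wfdb
#' @export
read_record_wfdb <- function(dir, name) {
  hea <- readLines(file.path(dir, paste0(name, ".hea")))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig <- strsplit(trimws(hea[2]), "\\s+")[[1]]
  adc_gain <- as.numeric(sub("/mV$", "", sig[3]))
  pid <- name
  cmt <- grep("^# patient_id ", hea, value = TRUE)
  if (length(cmt)) pid <- sub("^# patient_id ", "", cmt[1])
  con <- file(file.path(dir, paste0(name, ".dat")), "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = nsamp, size = 2L, endian = "little")
  x <- adc / adc_gain * 1000 # back to uv
  annf <- file.path(dir, paste0(name, ".ann.txt"))
  ann <- tibble(
    start_s = numeric(), end_s = numeric(), rhythm = character(),
    rate_bpm = numeric()
  )
  if (file.exists(annf)) {
    rows <- strsplit(readLines(annf), "\\s+")
    ann <- tibble(
      start_s = map_dbl(rows, ~ as.numeric(.x[1])),
      end_s = map_dbl(rows, ~ as.numeric(.x[2])),
      rhythm = vapply(rows, function(r) r[3], character(1)),
      rate_bpm = map_dbl(rows, ~ suppressWarnings(as.numeric(.x[4])))
    )
  }
  ecg_record(pid, fs, x, ann, record_id = name)
}
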