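#' @keywords internal
#' @useDynLib ecg2img, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Twelve-lead vocabulary
#'
#' Valid lead names for [waveform_record()]: the standard 12-lead set.
#' @export
LEAD_VOCABULARY <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG waveform record
#'
#' The canonical in-memory form of one patient's multi-lead ECG: a named list
#' of equal-length numeric amplitude vectors in millivolts, a sampling rate,
#' and an optional binary outcome label. A canonical full-length record holds
#' 10 s at 500 Hz, i.e. 5000 samples per lead.
#'
#' @param patient_id Opaque patient identifier (single string).
#' @param leads Named list of numeric vectors (mV). Names must come from the
#'   12-lead vocabulary (`LEAD_VOCABULARY`) and all vectors must have equal
#'   length.
#' @param sampling_rate_hz Sampling rate in Hz (positive; default 500).
#' @param label Optional outcome: `"survivor"` or `"non_survivor"`.
#' @return An object of class `ecg_waveform_record`.
#' @examples
#' rec <- waveform_record("p1", list(I = c(0.1, 0), II = c(0.2, 0.1)))
#' @export
waveform_record <- function(patient_id, leads, sampling_rate_hz = 500,
                            label = NULL) {
  assert_that(is.character(patient_id) && length(patient_id) == 1L &&
                nzchar(patient_id),
              "patient_id must be a non-empty string", "parse")
  assert_that(is.list(leads) && length(leads) >= 1L &&
                !is.null(names(leads)) && all(nzchar(names(leads))),
              "leads must be a non-empty named list", "empty_input")
  bad <- setdiff(names(leads), LEAD_VOCABULARY)
  assert_that(length(bad) == 0L,
              paste0("unknown lead name(s): ", paste(bad, collapse = ", ")),
              "parse")
  lens <- vapply(leads, length, integer(1))
  assert_that(all(lens == lens[[1L]]),
              "all lead sequences must have equal length", "shape")
  assert_that(lens[[1L]] >= 1L, "leads must contain at least one sample",
              "empty_input")
  assert_that(all(vapply(leads, is.numeric, logical(1))),
              "lead amplitudes must be numeric", "parse")
  assert_that(is.numeric(sampling_rate_hz) && length(sampling_rate_hz) == 1L &&
                sampling_rate_hz > 0,
              "sampling_rate_hz must be a positive number", "parse")
  if (!is.null(label)) {
    assert_that(label %in% c("survivor", "non_survivor"),
                "label must be 'survivor' or 'non_survivor'", "parse")
  }
  structure(
    list(patient_id = patient_id,
         leads = lapply(leads, as.numeric),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         label = label),
    class = "ecg_waveform_record"
  )
}

#' @export
print.ecg_waveform_record <- function(x, ...) {
  cat(sprintf("<ecg_waveform_record> patient %s: %d lead(s) [%s], %d samples @ %g Hz%s\n",
              x$patient_id, length(x$leads),
              paste(names(x$leads), collapse = ","),
              length(x$leads[[1L]]), x$sampling_rate_hz,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

n_samples <- function(record) length(record$leads[[1L]])

#' Read a waveform record from lead-per-column CSV
#'
#' The CSV interchange format: UTF-8, a header row naming the leads, one row
#' per sample, amplitudes in millivolts with `.` as the decimal point.
#'
#' @param path Path to the CSV file.
#' @param patient_id Patient identifier to attach to the record.
#' @param sampling_rate_hz Sampling rate of the stored samples (default 500).
#' @param label Optional outcome label.
#' @return An `ecg_waveform_record`.
#' @export
read_csv_waveform <- function(path, patient_id, sampling_rate_hz = 500,
                              label = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path), "parse")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) >= 2L,
              paste0("empty or header-only CSV: ", path), "empty_input")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    row <- which(widths != length(header))[[1L]] + 1L
    ecg_abort(sprintf("ragged CSV: row %d has %d field(s), expected %d",
                      row, widths[[row - 1L]], length(header)), "parse")
  }
  flat <- trimws(unlist(body, use.names = FALSE))
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) & !(flat %in% c("NA")))
  if (length(bad)) {
    row <- (bad[[1L]] - 1L) %/% length(header) + 2L
    ecg_abort(sprintf("non-numeric value '%s' in CSV row %d",
                      flat[[bad[[1L]]]], row), "parse")
  }
  mat <- matrix(vals, ncol = length(header), byrow = TRUE)
  leads <- lapply(seq_along(header), function(j) mat[, j])
  names(leads) <- header
  waveform_record(patient_id, leads, sampling_rate_hz, label)
}

#' Write a waveform record as lead-per-column CSV
#'
#' @param record An `ecg_waveform_record`.
#' @param path Output path.
#' @param digits Significant digits used when formatting amplitudes
#'   (default 10, ample for round-tripping synthetic data).
#' @return Invisibly, `path`.
#' @export
write_csv_waveform <- function(record, path, digits = 10) {
  stopifnot(inherits(record, "ecg_waveform_record"))
  mat <- do.call(cbind, record$leads)
  txt <- c(paste(names(record$leads), collapse = ","),
           apply(matrix(format(mat, digits = digits, trim = TRUE,
                               scientific = FALSE),
                        nrow = nrow(mat)), 1L, paste, collapse = ","))
  writeLines(txt, path)
  invisible(path)
}
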