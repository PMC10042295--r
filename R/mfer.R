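# Minimal MFER-style waveform container.
#
# MFER (Medical waveform Format Encoding Rules) is a tag-length-value
# standard for physiological waveforms. Hospital exports use the full
# standard; this module implements a deliberately small, fully documented
# subset with its own writer so fixtures can be generated and round-tripped
# without clinical files. The subset is NOT interoperable with full MFER.

MFER_MAGIC <- charToRaw("MFERSUB1")

# Tag map. Tags 0x01-0x3F are mandatory-to-understand: a reader hitting an
# unknown tag in that range must fail rather than skip. Tags 0x40-0xFF are
# optional annotations and are skipped when unknown.
MFER_TAG_CHANNELS   <- 0x01L # uint16 LE, number of waveform channels
MFER_TAG_INTERVAL   <- 0x02L # float64 LE, sampling interval in seconds
MFER_TAG_RESOLUTION <- 0x03L # float64 LE, amplitude resolution in mV/LSB
MFER_TAG_LEADNAME   <- 0x08L # ASCII, lead name of the next waveform block
MFER_TAG_WAVEFORM   <- 0x09L # int16 LE samples, amplitude = value*resolution
MFER_TAG_PATIENT    <- 0x41L # ASCII patient id (optional)
MFER_TAG_LABEL      <- 0x42L # ASCII outcome label (optional)

#' Write a waveform record as a minimal MFER-subset fixture
#'
#' Serialises a record into a small tag-length-value binary container
#' patterned on the MFER waveform standard. Byte layout:
#'
#' @section Byte layout:
#' The file starts with the 8-byte magic `"MFERSUB1"`, followed by a sequence
#' of tag-length-value (TLV) records: 1-byte tag, 4-byte little-endian
#' unsigned length, then `length` value bytes. Tags `0x01` (channel count,
#' uint16 LE), `0x02` (sampling interval in seconds, float64 LE) and `0x03`
#' (amplitude resolution in mV per unit, float64 LE) must appear before any
#' waveform block. Each waveform block is a `0x08` lead-name record (ASCII)
#' immediately followed by a `0x09` sample record holding little-endian
#' signed 16-bit integers; amplitude in mV = integer * resolution. Tags
#' `0x41`/`0x42` optionally carry the patient id and outcome label. Tags in
#' `0x01`-`0x3F` are mandatory-to-understand; unknown optional tags
#' (`0x40`-`0xFF`) are skipped on read.
#'
#' Writing is deterministic: the same record always produces identical bytes.
#' Amplitudes are quantised to `resolution_mv`; a record whose amplitudes are
#' already integer multiples of the resolution round-trips exactly.
#'
#' @param record An `ecg_waveform_record`.
#' @param path Output path.
#' @param resolution_mv Amplitude resolution in mV per integer unit
#'   (default 0.001, i.e. 1 microvolt per LSB).
#' @return Invisibly, `path`.
#' @export
write_mfer_fixture <- function(record, path, resolution_mv = 1e-3) {
  stopifnot(inherits(record, "ecg_waveform_record"))
  assert_that(length(record$leads) >= 1L, "record has no leads", "empty_input")
  assert_that(resolution_mv > 0, "resolution must be positive", "parse")

  enc_u32 <- function(n) writeBin(as.integer(n), raw(), size = 4L,
                                  endian = "little")
  tlv <- function(tag, value_raw) {
    if (length(value_raw) > 2^31 - 1)
      ecg_abort("TLV value exceeds 32-bit length field", "capacity")
    c(as.raw(tag), enc_u32(length(value_raw)), value_raw)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  out <- list(MFER_MAGIC)
  out <- c(out, list(
    tlv(MFER_TAG_CHANNELS, writeBin(length(record$leads), raw(), size = 2L,
                                    endian = "little")),
    tlv(MFER_TAG_INTERVAL, writeBin(1 / record$sampling_rate_hz, raw(),
                                    size = 8L, endian = "little")),
    tlv(MFER_TAG_RESOLUTION, writeBin(as.numeric(resolution_mv), raw(),
                                      size = 8L, endian = "little")),
    tlv(MFER_TAG_PATIENT, charToRaw(record$patient_id))
  ))
  if (!is.null(record$label))
    out <- c(out, list(tlv(MFER_TAG_LABEL, charToRaw(record$label))))
  for (nm in names(record$leads)) {
    q <- round(record$leads[[nm]] / resolution_mv)
    if (any(abs(q) > 32767))
      ecg_abort(sprintf(
        "lead %s exceeds int16 range at resolution %g mV/LSB", nm,
        resolution_mv), "capacity")
    if (2 * length(q) > 2^31 - 1)
      ecg_abort("lead too long for 32-bit length field", "capacity")
    out <- c(out, list(
      tlv(MFER_TAG_LEADNAME, charToRaw(nm)),
      tlv(MFER_TAG_WAVEFORM, writeBin(as.integer(q), raw(), size = 2L,
                                      endian = "little"))
    ))
  }
  writeBin(unlist(out), con)
  invisible(path)
}

#' Read a minimal MFER-subset waveform file
#'
#' Decodes the TLV container written by [write_mfer_fixture()] (see that
#' function's documentation for the byte layout). The sampling rate is
#' reconstructed from the stored sampling interval and raw integer samples
#' are scaled to millivolts by the stored amplitude resolution.
#'
#' @param path Path to the file.
#' @return An `ecg_waveform_record`.
#' @export
read_mfer_subset <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path), "parse")
  bytes <- readBin(path, raw(), n = file.size(path))
  assert_that(length(bytes) >= length(MFER_MAGIC) &&
                identical(bytes[seq_along(MFER_MAGIC)], MFER_MAGIC),
              "not an MFER-subset file (bad magic)", "unsupported_format")
  pos <- length(MFER_MAGIC) + 1L
  n_bytes <- length(bytes)

  channels <- NULL; interval <- NULL; resolution <- NULL
  patient_id <- "unknown"; label <- NULL
  leads <- list(); pending_name <- NULL

  dec_int <- function(r, size, signed = TRUE)
    readBin(r, "integer", n = length(r) %/% size, size = size,
            endian = "little", signed = signed)
  dec_dbl <- function(r) readBin(r, "double", n = 1L, size = 8L,
                                 endian = "little")

  while (pos <= n_bytes) {
    tag <- as.integer(bytes[[pos]])
    if (pos + 4L > n_bytes)
      ecg_abort("truncated TLV header", "truncation")
    len <- sum(as.integer(bytes[(pos + 1L):(pos + 4L)]) * 256^(0:3))
    v0 <- pos + 5L
    if (v0 + len - 1L > n_bytes)
      ecg_abort(sprintf("truncated value for tag 0x%02X", tag), "truncation")
    val <- if (len > 0) bytes[v0:(v0 + len - 1L)] else raw()
    if (tag == MFER_TAG_CHANNELS) {
      channels <- dec_int(val, 2L, signed = FALSE)
    } else if (tag == MFER_TAG_INTERVAL) {
      interval <- dec_dbl(val)
    } else if (tag == MFER_TAG_RESOLUTION) {
      resolution <- dec_dbl(val)
    } else if (tag == MFER_TAG_LEADNAME) {
      pending_name <- rawToChar(val)
    } else if (tag == MFER_TAG_WAVEFORM) {
      assert_that(!is.null(pending_name),
                  "waveform block without a preceding lead name",
                  "unsupported_format")
      assert_that(!is.null(resolution),
                  "waveform block before amplitude resolution",
                  "unsupported_format")
      leads[[pending_name]] <- dec_int(val, 2L) * resolution
      pending_name <- NULL
    } else if (tag == MFER_TAG_PATIENT) {
      patient_id <- rawToChar(val)
    } else if (tag == MFER_TAG_LABEL) {
      label <- rawToChar(val)
    } else if (tag <= 0x3F) {
      ecg_abort(sprintf("unknown mandatory tag 0x%02X", tag),
                "unsupported_format")
    } # optional unknown tag: skip
    pos <- v0 + len
  }

  assert_that(!is.null(channels) && !is.null(interval),
              "missing channel-count or sampling-interval record",
              "unsupported_format")
  assert_that(channels >= 1L, "file declares zero channels", "empty_input")
  if (length(leads) < channels)
    ecg_abort(sprintf("declared %d channel(s) but found %d waveform block(s)",
                      channels, length(leads)), "truncation")
  waveform_record(patient_id, leads, sampling_rate_hz = 1 / interval,
                  label = label)
}
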