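test_that("CSV waveforms parse by column with sample order preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("I,II", "0.1,0.2", "0.0,0.1", "-0.1,0.0"), path)
  rec <- read_csv_waveform(path, "p1")
  expect_s3_class(rec, "ecg_waveform_record")
  expect_equal(rec$leads$I, c(0.1, 0.0, -0.1))
  expect_equal(rec$leads$II, c(0.2, 0.1, 0.0))
  expect_equal(rec$sampling_rate_hz, 500)
})

test_that("CSV write/read round-trips a synthetic record", {
  rec <- gen_patient("non_survivor", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_waveform(rec, path)
  back <- read_csv_waveform(path, rec$patient_id, label = rec$label)
  expect_identical(names(back$leads), names(rec$leads))
  for (nm in names(rec$leads))
    expect_equal(back$leads[[nm]], rec$leads[[nm]], tolerance = 1e-8)
  # no reordering: the written and re-read lead align at lag zero
  cc <- stats::ccf(back$leads$II, rec$leads$II, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("malformed CSVs fail with the offending row named", {
  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("I,II", "0.1,0.2", "0.3"), ragged)
  expect_error(read_csv_waveform(ragged, "p"), "row 3",
               class = "ecg2img_parse_error")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("I,II", "0.1,abc"), nonnum)
  expect_error(read_csv_waveform(nonnum, "p"), "row 2",
               class = "ecg2img_parse_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_error(read_csv_waveform(empty, "p"),
               class = "ecg2img_empty_input_error")
})

test_that("waveform records enforce their invariants", {
  expect_error(waveform_record("p", list(I = 1:3, II = 1:2)),
               class = "ecg2img_shape_error")
  expect_error(waveform_record("p", list(XX = 1:3)),
               class = "ecg2img_parse_error")
  expect_error(waveform_record("p", list()),
               class = "ecg2img_empty_input_error")
})

test_that("MFER fixtures match the documented byte layout (hand-decoded)", {
  rec <- waveform_record("pz", list(II = numeric(10)))
  path <- withr::local_tempfile(fileext = ".mfer")
  write_mfer_fixture(rec, path)
  bytes <- readBin(path, raw(), n = file.size(path))
  expect_identical(bytes[1:8], charToRaw("MFERSUB1"))
  p <- 9L
  read_tlv <- function() {
    tag <- as.integer(bytes[[p]])
    len <- sum(as.integer(bytes[(p + 1L):(p + 4L)]) * 256^(0:3))
    val <- if (len > 0) bytes[(p + 5L):(p + 4L + len)] else raw()
    p <<- p + 5L + len
    list(tag = tag, len = len, val = val)
  }
  t1 <- read_tlv()   # channel count, uint16 LE
  expect_equal(t1$tag, 0x01)
  expect_equal(as.integer(t1$val), c(1L, 0L))
  t2 <- read_tlv()   # sampling interval, float64 LE
  expect_equal(t2$tag, 0x02)
  expect_equal(readBin(t2$val, "double", 1, 8, endian = "little"), 1 / 500)
  t3 <- read_tlv()   # resolution, float64 LE
  expect_equal(t3$tag, 0x03)
  expect_equal(readBin(t3$val, "double", 1, 8, endian = "little"), 1e-3)
  t4 <- read_tlv()   # patient id
  expect_equal(t4$tag, 0x41)
  expect_equal(rawToChar(t4$val), "pz")
  t5 <- read_tlv()   # lead name
  expect_equal(t5$tag, 0x08)
  expect_equal(rawToChar(t5$val), "II")
  t6 <- read_tlv()   # ten zero int16 samples
  expect_equal(t6$tag, 0x09)
  expect_equal(t6$len, 20)
  expect_true(all(t6$val == as.raw(0)))
  expect_equal(p, length(bytes) + 1L)

  back <- read_mfer_subset(path)
  expect_equal(back$leads$II, numeric(10))
})

test_that("MFER round-trip preserves grid-aligned amplitudes to 1e-6 mV", {
  rec <- grid_aligned_record(seed = 11)
  path <- withr::local_tempfile(fileext = ".mfer")
  write_mfer_fixture(rec, path)
  back <- read_mfer_subset(path)
  expect_identical(back$patient_id, rec$patient_id)
  expect_equal(back$sampling_rate_hz, rec$sampling_rate_hz)
  expect_identical(back$label, rec$label)
  for (nm in names(rec$leads)) {
    expect_equal(length(back$leads[[nm]]), length(rec$leads[[nm]]))
    expect_lt(max(abs(back$leads[[nm]] - rec$leads[[nm]])), 1e-6)
  }
  # arbitrary (unaligned) records stay within the quantisation bound
  raw_rec <- gen_patient("survivor", seed = 12)
  write_mfer_fixture(raw_rec, path)
  back2 <- read_mfer_subset(path)
  expect_lt(max(abs(back2$leads$II - raw_rec$leads$II)), 5e-4 + 1e-12)
})

test_that("MFER writing is deterministic and errors are classed", {
  rec <- grid_aligned_record(seed = 2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_mfer_fixture(rec, p1)
  write_mfer_fixture(rec, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))

  # amplitude exceeding the int16 range at the default resolution
  big <- waveform_record("p", list(II = c(0, 40)))
  expect_error(write_mfer_fixture(big, p1), class = "ecg2img_capacity_error")

  # record with no leads (bypassing the constructor)
  hollow <- structure(list(patient_id = "p", leads = list(),
                           sampling_rate_hz = 500, label = NULL),
                      class = "ecg_waveform_record")
  expect_error(write_mfer_fixture(hollow, p1),
               class = "ecg2img_empty_input_error")
})

test_that("MFER reader rejects malformed containers", {
  rec <- waveform_record("p", list(II = c(0, 0.001), V3 = c(0.002, 0)))
  path <- withr::local_tempfile()
  write_mfer_fixture(rec, path)
  bytes <- readBin(path, raw(), file.size(path))

  # truncated mid-value
  writeBin(bytes[1:(length(bytes) - 2L)], path)
  expect_error(read_mfer_subset(path), class = "ecg2img_truncation_error")

  # channel count says 2 but only 1 waveform block present: drop the final
  # lead-name + waveform TLVs (II block = 2+5+4 + 4+5 = 20 bytes at the tail)
  one_lead <- waveform_record("p", list(II = c(0, 0.001)))
  write_mfer_fixture(one_lead, path)
  b <- readBin(path, raw(), file.size(path))
  # first TLV: tag byte 9, length bytes 10-13, uint16 channel count at 14-15
  b[14] <- as.raw(2)
  writeBin(b, path)
  expect_error(read_mfer_subset(path), "2 channel",
               class = "ecg2img_truncation_error")

  # zero channels
  b[14] <- as.raw(0)
  writeBin(b, path)
  expect_error(read_mfer_subset(path), class = "ecg2img_empty_input_error")

  # unknown mandatory tag
  b[14] <- as.raw(1)
  b[9] <- as.raw(0x1F)
  writeBin(b, path)
  expect_error(read_mfer_subset(path),
               class = "ecg2img_unsupported_format_error")

  # bad magic
  b[1] <- as.raw(0x00)
  writeBin(b, path)
  expect_error(read_mfer_subset(path),
               class = "ecg2img_unsupported_format_error")
})
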