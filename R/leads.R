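#' Fixed lead order of the four-lead imaging panel
#' @export
PANEL_LEADS <- c("II", "V3", "V5", "aVR")

#' Derive the augmented lead aVR from limb leads I and II
#'
#' The augmented right-arm lead is an arithmetic combination of the two
#' Einthoven limb leads: `aVR(t) = -((I(t) + II(t)) / 2)`, applied
#' element-wise. Bedside monitors display aVR by exactly this arithmetic, so
#' records that lack a stored aVR channel can always be completed from I
#' and II.
#'
#' @param lead_i,lead_ii Equal-length numeric vectors of amplitudes (mV).
#' @return Numeric vector of aVR amplitudes (mV).
#' @examples
#' derive_avr(c(2), c(4))   # -3
#' @export
derive_avr <- function(lead_i, lead_ii) {
  assert_that(length(lead_i) >= 1L && length(lead_ii) >= 1L,
              "lead inputs must be non-empty", "empty_input")
  assert_that(length(lead_i) == length(lead_ii),
              sprintf("lead length mismatch: %d vs %d",
                      length(lead_i), length(lead_ii)), "shape")
  -((as.numeric(lead_i) + as.numeric(lead_ii)) / 2)
}

#' Construct a four-lead imaging panel
#'
#' @param patient_id Patient identifier.
#' @param leads_in_order Named list of exactly four equal-length numeric
#'   vectors, in the fixed order II, V3, V5, aVR.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `ecg_lead_panel`.
#' @export
lead_panel <- function(patient_id, leads_in_order, sampling_rate_hz = 500) {
  assert_that(is.list(leads_in_order) && length(leads_in_order) == 4L,
              "a lead panel holds exactly four leads", "shape")
  assert_that(identical(names(leads_in_order), PANEL_LEADS),
              paste0("panel leads must be, in order: ",
                     paste(PANEL_LEADS, collapse = ", ")), "shape")
  lens <- lengths(leads_in_order)
  assert_that(all(lens == lens[[1L]]) && lens[[1L]] >= 1L,
              "panel leads must be non-empty and of equal length", "shape")
  structure(
    list(patient_id = patient_id,
         leads_in_order = lapply(leads_in_order, as.numeric),
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "ecg_lead_panel"
  )
}

#' @export
print.ecg_lead_panel <- function(x, ...) {
  cat(sprintf("<ecg_lead_panel> patient %s: %s, %d samples @ %g Hz\n",
              x$patient_id, paste(PANEL_LEADS, collapse = "/"),
              length(x$leads_in_order[[1L]]), x$sampling_rate_hz))
  invisible(x)
}

#' Select the four-lead imaging panel from a waveform record
#'
#' Picks leads II, V3 and V5 from the record and completes the panel with
#' aVR: a stored aVR channel is passed through unchanged; otherwise aVR is
#' derived from leads I and II via [derive_avr()].
#'
#' @param record An `ecg_waveform_record` containing II, V3, V5 and either
#'   aVR or both I and II.
#' @return An `ecg_lead_panel` in the fixed order II, V3, V5, aVR.
#' @export
select_panel <- function(record) {
  stopifnot(inherits(record, "ecg_waveform_record"))
  for (nm in c("II", "V3", "V5")) {
    if (is.null(record$leads[[nm]]))
      ecg_abort(paste0("missing required lead: ", nm), "missing_lead")
  }
  avr <- record$leads[["aVR"]]
  if (is.null(avr)) {
    if (is.null(record$leads[["I"]]))
      ecg_abort("missing required lead: aVR (and no I to derive it from)",
                "missing_lead")
    avr <- derive_avr(record$leads[["I"]], record$leads[["II"]])
  }
  lead_panel(record$patient_id,
             list(II = record$leads[["II"]], V3 = record$leads[["V3"]],
                  V5 = record$leads[["V5"]], aVR = avr),
             record$sampling_rate_hz)
}
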