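# Structured error conditions. Every user-facing failure mode carries a
# condition class of the form "ecg2img_<kind>_error" so callers and tests can
# dispatch on the kind rather than match message text.

ecg_abort <- function(msg, kind, ...) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("ecg2img_", kind, "_error"), "ecg2img_error")
  ))
}

# shorthand validators used across modules
assert_that <- function(ok, msg, kind) {
  if (!isTRUE(ok)) ecg_abort(msg, kind)
  invisible(TRUE)
}
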