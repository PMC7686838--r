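# Typed conditions: every domain error carries a class so callers can route
# records to quarantine instead of aborting a run.

stop_sq <- function(reason, msg) {
  cond <- structure(
    class = c(paste0("sq_", reason), "sq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), reason = reason)
  )
  stop(cond)
}

sq_reason <- function(cond) {
  if (!is.null(cond$reason)) cond$reason else "error"
}

# Number formatting for URLs: plain decimal notation, no trailing zeros.
format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}
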