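# Structured error conditions. Every error raised by the package carries the
# class "cg_error" plus a specific subclass so callers can trap one failure
# mode without string-matching messages.

cg_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "cg_error")))
}

cg_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) cg_abort(class, msg, ...)
  invisible(TRUE)
}
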