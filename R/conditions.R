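# Structured conditions: every user-facing failure carries a subclass of
# "lnm_error" so callers (and the CLI) can distinguish config, data and
# computation faults without parsing messages.

lnm_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "lnm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
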