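# Classed conditions so callers (and the CLI) can distinguish I/O failures
# from modelling failures without string-matching messages.

nsb_condition <- function(message, class, call = sys.call(-1)) {
  structure(
    class = c(class, "nsb_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_model_error <- function(message, call = sys.call(-1)) {
  stop(nsb_condition(message, "nsb_model_error", call))
}

stop_io_error <- function(message, call = sys.call(-1)) {
  stop(nsb_condition(message, "nsb_io_error", call))
}

# Minimal structured logging: everything to stderr, prefixed.
nsb_log <- function(fmt, ...) {
  message(sprintf(paste0("[nsbforecast] ", fmt), ...))
}
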