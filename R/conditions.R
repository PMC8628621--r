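# Classed conditions so callers (and the CLI) can distinguish parse failures
# from validation/matching failures.

ptb_stop <- function(message, class, call = sys.call(-1L)) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_parse <- function(...) {
  ptb_stop(paste0(...), "ptb_parse_error", call = sys.call(-1L))
}

stop_validation <- function(...) {
  ptb_stop(paste0(...), "ptb_validation_error", call = sys.call(-1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
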