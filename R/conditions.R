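# Condition helpers: input/validation problems and numerical failures carry
# distinct classes so callers (and the CLI) can map them to exit codes.

stop_input <- function(fmt, ..., call. = FALSE) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("karyorate_input_error", "error")))
}

stop_numeric <- function(fmt, ..., call. = FALSE) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("karyorate_numeric_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
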