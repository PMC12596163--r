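# Typed condition helpers. All user-facing failures go through these so
# callers (and tests) can dispatch on condition class instead of matching
# message text.

ec_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ecnorm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) ec_abort(msg, "ecnorm_validation_error", ...)
abort_key        <- function(msg, ...) ec_abort(msg, "ecnorm_key_error", ...)
abort_estimation <- function(msg, ...) ec_abort(msg, "ecnorm_estimation_error", ...)
abort_io         <- function(msg, ...) ec_abort(msg, "ecnorm_io_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
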