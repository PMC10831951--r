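# Classed conditions so callers (and the CLI exit-code mapping) can tell
# invalid inputs apart from numerical failures.

stop_validation <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("frapkit_validation_error", "error")))
}

stop_numeric <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("frapkit_numeric_error", "error")))
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (x < min || x > max) {
    stop_validation(name, " must be in [", min, ", ", max, "], got ", x)
  }
  if (integer && x != round(x)) stop_validation(name, " must be an integer, got ", x)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
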