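# Classed error conditions so callers can discriminate failure modes.

stop_cellpopfit <- function(subclass, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(paste0("cellpopfit_", subclass), "cellpopfit_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

stop_invalid_input <- function(message, ...) {
  stop_cellpopfit("invalid_input", message, call = sys.call(-1), ...)
}

stop_insufficient_data <- function(message, ...) {
  stop_cellpopfit("insufficient_data", message, call = sys.call(-1), ...)
}

stop_numerical <- function(message, ...) {
  stop_cellpopfit("numerical_error", message, call = sys.call(-1), ...)
}

check_times <- function(times, what = "times") {
  if (!is.numeric(times) || length(times) == 0L) {
    stop_invalid_input(sprintf("`%s` must be a nonempty numeric vector", what))
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop_invalid_input(sprintf("`%s` contains missing or non-finite values", what))
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_invalid_input(sprintf("`%s` must be strictly increasing", what))
  }
  invisible(as.numeric(times))
}

check_nonneg_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_invalid_input(sprintf("`%s` must be a single nonnegative number", what))
  }
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
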