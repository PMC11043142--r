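# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
abort_varburden <- function(msg, class = "varburden_error", ...) {
  rlang::abort(msg, class = c(class, "varburden_error"), ...)
}

# Derive a deterministic substream seed for a pipeline stage from the global
# seed. Offsets are fixed per stage so stages are independently reproducible.
# Result kept within 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

check_fraction <- function(x, name, open_zero = TRUE, closed_one = TRUE) {
  lo_ok <- if (open_zero) x > 0 else x >= 0
  hi_ok <- if (closed_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    abort_varburden(sprintf(
      "`%s` must be a single number in %s0, 1%s, got %s",
      name, if (open_zero) "(" else "[", if (closed_one) "]" else ")",
      paste(format(x), collapse = ", ")
    ), class = "varburden_validation_error")
  }
  invisible(x)
}
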