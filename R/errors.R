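# Condition classes shared across the package. All inherit "fbdg_error" so
# callers can catch everything from this package with one class.

stop_validation <- function(message, ...) {
  abort(message, class = c("fbdg_validation_error", "fbdg_error"), ...)
}

stop_missing_reference <- function(message, commodity = NULL, step = NULL, ...) {
  abort(
    message,
    class = c("fbdg_missing_reference_error", "fbdg_error"),
    commodity = commodity, step = step, ...
  )
}

stop_empty_group <- function(message, country = NULL, group = NULL, ...) {
  abort(
    message,
    class = c("fbdg_empty_group_error", "fbdg_error"),
    country = country, group = group, ...
  )
}

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    stop_validation(sprintf("`%s` must be finite.", name))
  }
  if (strict && x <= min) {
    stop_validation(sprintf("`%s` must be > %g (got %g).", name, min, x))
  }
  if (!strict && x < min) {
    stop_validation(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  }
  invisible(x)
}
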