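# Internal input-validation helpers shared across the package.

stopf <- function(fmt, ..., class = "pewrisk_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

check_numeric <- function(x, name, lower = -Inf, allow_lower = TRUE) {
  if (!is.numeric(x) || length(x) == 0) {
    stopf("'%s' must be a non-empty numeric vector", name,
          class = "pewrisk_invalid_input")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("'%s' contains missing or non-finite values", name,
          class = "pewrisk_invalid_input")
  }
  bad <- if (allow_lower) x < lower else x <= lower
  if (any(bad)) {
    stopf("'%s' must be %s %g (offending value: %g)", name,
          if (allow_lower) ">=" else ">", lower, x[which(bad)[1]],
          class = "pewrisk_invalid_input")
  }
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
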