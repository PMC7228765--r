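#' @keywords internal
#' @noRd
abort_dicckit <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "dicckit_error"), ...)
}

# Validation / configuration problems: the CLI maps these to exit code 2,
# everything else (runtime failures) to exit code 1.
#' @noRd
abort_config <- function(message, ...) {
  abort_dicckit(message, class = c("dicckit_config_error"), ...)
}

#' @noRd
check_scalar_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  if (integerish && x != round(x)) {
    abort_config(sprintf("`%s` must be a whole number.", name))
  }
  if (x < min || x > max) {
    abort_config(sprintf("`%s` must be in [%s, %s].", name, min, max))
  }
  invisible(x)
}
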