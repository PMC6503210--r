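# Classed conditions so callers can distinguish failure modes programmatically.
# Every error is a "ppc_error"; the first class names the specific mode,
# e.g. ppc_invalid_config_error, ppc_detection_failure_error.

ppc_stop <- function(type, msg, ...) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("ppc_", type, "_error"), "ppc_error")
  ))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ppc_stop("invalid_config", "'%s' must be a single finite number", name)
  if (strict_min && x <= min)
    ppc_stop("invalid_config", "'%s' must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min)
    ppc_stop("invalid_config", "'%s' must be >= %g (got %g)", name, min, x)
  invisible(x)
}
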