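#' @keywords internal
#' @useDynLib redudim, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Classed conditions so callers can distinguish parameter errors from
# numerical-stability errors programmatically.

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("redudim_invalid_parameter", "redudim_error")))
}

stop_stability <- function(msg, report) {
  stop(errorCondition(msg, report = report,
                      class = c("redudim_stability_error", "redudim_error")))
}

stop_not_converged <- function(msg) {
  stop(errorCondition(msg, class = c("redudim_not_converged", "redudim_error")))
}

stop_unsupported <- function(msg) {
  stop(errorCondition(msg, class = c("redudim_unsupported_scheme", "redudim_error")))
}

warn_redudim <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "redudim_warning")))
}
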