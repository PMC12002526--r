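# Internal helpers. Terse on purpose.

# dim-preserving clamp (pmin/pmax take attributes from their first argument)
.clamp <- function(x, lo, hi) { x[x < lo] <- lo; x[x > hi] <- hi; x }

# round half away from zero (base round() is banker's rounding)
.roundHalfAway <- function(x) trunc(x + sign(x) * 0.5)

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == trunc(x)

.isProb <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

#' Emit a timestamped log line on standard error
#'
#' Logging is suppressed when `options(sphereInsight.verbose = FALSE)`.
#'
#' @param level one of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... message parts, pasted without separator.
#' @return invisibly, the formatted line.
#' @keywords internal
siLog <- function(level = "INFO", ...) {
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = ""))
  if (isTRUE(getOption("sphereInsight.verbose", TRUE))) {
    cat(line, "\n", file = stderr(), sep = "")
  }
  invisible(line)
}

# unit-norm check with tolerance
.assertUnit <- function(v, tol = 1e-8, what = "vector") {
  if (abs(sqrt(sum(v^2)) - 1) > tol) {
    stop(sprintf("%s must have unit norm (|1 - norm| = %.3g > %.3g)",
                 what, abs(sqrt(sum(v^2)) - 1), tol), call. = FALSE)
  }
  invisible(TRUE)
}
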