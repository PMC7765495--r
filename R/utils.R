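#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# logistic function, numerically safe for large |x|
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin validated wrapper around [stats::p.adjust()] used by every
#' detector to turn raw p-values into FDR-adjusted ones.
#'
#' @param p numeric vector of raw p-values in \[0, 1\]; `NA` is rejected.
#' @param method adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return numeric vector of adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (!is.numeric(p)) stopf("p-values must be numeric")
  if (anyNA(p)) stopf("p-values contain NA/NaN")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
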