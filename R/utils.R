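#' Round half away from zero
#'
#' Presentation rounding for attributable counts and PAF percentages.
#' `base::round()` rounds half to even; published burden tables round
#' half away from zero, so 392.5 prints as 393 and -0.5 as -1.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(392.5) # 393, where round() gives 392
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop() with a prefix-free, sprintf-style message
abort_paf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_paf("`%s` must be numeric and non-missing", name)
  }
  if (any(x < lower) || any(x > upper)) {
    abort_paf("`%s` must lie in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}
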