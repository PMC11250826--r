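#' Round half away from zero
#'
#' Deterministic rounding used throughout the package in place of base
#' \code{round()}, whose IEC 60559 banker's rounding is platform-sensitive at
#' exact halves. Used for multiplicity assignment and report percentages.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up (away from zero)
#' @export
#' @examples
#' roundHalfUp(2.5)   # 3, where round(2.5) gives 2
#' roundHalfUp(0.125, 2)
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a count as a percentage to one decimal
#'
#' @param k numerator count
#' @param n denominator count
#' @return numeric percentage rounded half-up to one decimal
#' @export
#' @examples
#' pctOf(70, 778)   # 9.0
pctOf <- function(k, n) {
  stopifnot(n > 0)
  roundHalfUp(100 * k / n, 1)
}

## internal: stop unless all named conditions hold, with a compact message
.assertThat <- function(...) {
  conds <- list(...)
  nm <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(nm[i], call. = FALSE)
  }
  invisible(TRUE)
}

## internal: seeds derived from one master seed, kept inside 32-bit range
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299709) %% 2147483647L)
}
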