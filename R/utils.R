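## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reporting convention for printed agreement tables: ties round away from
#' zero (so 0.125 -> 0.13 and -0.125 -> -0.13), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
#' @examples
#' roundHalfAway(c(-17.256, 50.756, 0.552), 2)
roundHalfAway <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Clip to the 8-bit range and round to integers.
clip8bit <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

## Evaluate code under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Integer-checking convenience.
isCount <- function(x, min = 1) {
  length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
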