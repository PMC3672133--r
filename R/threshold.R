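#' Calculated intensity threshold separating tissue from open space
#'
#' Otsu's criterion on the 256-bin intensity histogram: the returned
#' threshold maximises the between-class variance of the two classes
#' `{intensity < t}` and `{intensity >= t}`; the smallest maximiser is
#' returned. Deterministic.
#'
#' @param image a [BScanImage-class].
#' @return a single intensity threshold in (0, 255\].
#' @export
#' @examples
#' ph <- renderBScan(AnteriorSegmentGeometry(), noiseFree())
#' computeThreshold(bscanImage(ph))
computeThreshold <- function(image) {
  stopifnot(is(image, "BScanImage"))
  p <- as.integer(image@pixels)
  if (!length(p)) stop("empty image")
  h <- tabulate(p + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) stop("degenerate histogram")
  lev <- 0:255
  cw <- cumsum(h)                 # count of intensities <= k
  cm <- cumsum(h * lev)           # intensity-weighted cumulative sum
  n <- cw[256L]; total <- cm[256L]
  ## candidate thresholds t = 1..255; class 0 is {< t} i.e. <= t-1
  w0 <- cw[1:255]
  w1 <- n - w0
  m0 <- cm[1:255]
  valid <- w0 > 0L & w1 > 0L
  bcv <- rep(-Inf, 255L)
  mu0 <- m0[valid] / w0[valid]
  mu1 <- (total - m0[valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  which.max(bcv)                  # threshold t; smallest argmax
}

#' Binarize a B-scan against a threshold
#'
#' Pixels at or above the threshold become 1 (tissue), the rest 0 (open
#' space); the threshold is recorded in the result.
#'
#' @param image a [BScanImage-class].
#' @param threshold intensity in \[0, 256\] (256 marks every pixel as open
#'   space).
#' @return a [BinaryImage-class].
#' @export
binarize <- function(image, threshold) {
  stopifnot(is(image, "BScanImage"))
  if (!is.finite(threshold) || threshold < 0 || threshold > 256)
    stop("threshold must lie in [0, 256]")
  b <- (image@pixels >= threshold) * 1
  new("BinaryImage", pixels = b, thresholdUsed = threshold)
}
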