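#' Smooth raw border points and fit a polynomial trace
#'
#' Repairs step-like portions of a raw border with a running median of
#' width `smoothingWindow` over the non-missing points (missing columns are
#' skipped, not interpolated), least-squares-fits a polynomial of the given
#' degree in centred column coordinates, discards points whose absolute
#' residual exceeds `outlierTol`, and refits once.
#'
#' Integer-valued inputs are treated as axially quantized edge rows: a
#' detected row `d` certifies that the boundary crosses that column within
#' `(d - 1, d]`. The refit therefore uses sub-pixel data: wherever the
#' (smoothed, outlier-pruned) staircase steps by one row between nearby
#' columns, the boundary crosses the shared integer level at the column
#' midpoint, giving a near-exact point on the curve; the final polynomial
#' is fitted to these level-crossing points when at least `degree + 6` of
#' them exist, and to the interval midpoints `d - 0.5` otherwise. Either
#' way the fit estimates the continuous boundary, not the staircase.
#' Non-integer inputs are fitted as-is (`quantized = FALSE`), so points
#' sampled exactly from a polynomial are reproduced exactly.
#'
#' @param x 0-based column positions (strictly increasing).
#' @param y raw detected rows; NA marks columns where detection failed.
#' @param degree polynomial degree.
#' @param smoothingWindow odd running-median width (capped at the number of
#'   detected points).
#' @param outlierTol residual cutoff in pixels for the single refit pass.
#' @param label trace label (see [BoundaryTrace-class]).
#' @param quantized treat `y` as integer-quantized edge rows; by default
#'   auto-detected (TRUE iff all detected rows are whole numbers).
#' @return a [BoundaryTrace-class] carrying both the raw points and the
#'   fitted polynomial.
#' @export
smoothAndFit <- function(x, y, degree = 4L, smoothingWindow = 11L,
                         outlierTol = 3, label = "epithelium",
                         quantized = NULL) {
  stopifnot(length(x) == length(y), smoothingWindow >= 1L,
            smoothingWindow %% 2L == 1L, degree >= 0L)
  keep <- !is.na(y)
  if (sum(keep) < degree + 6L) stop("insufficient border support")
  xk <- x[keep]; yk <- y[keep]
  if (is.null(quantized)) quantized <- all(yk == round(yk))
  k <- min(smoothingWindow, length(yk) - (length(yk) + 1L) %% 2L)
  ys <- if (k >= 3L) stats::runmed(yk, k, endrule = "median") else yk
  center <- mean(xk)
  fitOnce <- function(xv, yv) {
    stats::lm.fit(outer(xv - center, 0:degree, "^"), yv)
  }
  f1 <- fitOnce(xk, ys)
  good <- abs(f1$residuals) <= outlierTol
  if (sum(good) < degree + 6L) good <- rep(TRUE, length(xk))
  xg <- xk[good]; yg <- ys[good]
  if (quantized) {
    ## sub-pixel refit from level crossings of the pruned staircase
    i <- which(abs(diff(yg)) == 1 & diff(xg) <= 2)
    if (length(i) >= degree + 6L) {
      f2 <- fitOnce((xg[i] + xg[i + 1L]) / 2, pmin(yg[i], yg[i + 1L]))
    } else {
      f2 <- fitOnce(xg, yg - 0.5)
    }
  } else {
    f2 <- if (all(good)) f1 else fitOnce(xg, yg)
  }
  co <- unname(f2$coefficients)
  co[is.na(co)] <- 0
  new("BoundaryTrace", x = as.numeric(x), yRaw = as.numeric(y),
      coefficients = co, fitCenter = center,
      fitDomain = range(xg), label = label)
}
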