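#' Bland-Altman plot
#'
#' Scatter of differences against averages with the zero line, the mean
#' difference, the 95% limits of agreement with shaded confidence
#' intervals; in proportional-bias mode the difference-on-average
#' regression line and its 95% prediction band replace the horizontal
#' limits.
#'
#' @param series a [PairedSeries-class].
#' @param result matching [BlandAltmanResult-class]; computed if omitted.
#' @param proportional draw regression + prediction band instead of
#'   horizontal limits.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return the result object, invisibly.
#' @export
blandAltmanPlot <- function(series, result = blandAltman(series),
                            proportional = FALSE, file = NULL,
                            main = NULL) {
  stopifnot(is(series, "PairedSeries"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  a <- series@valuesA; b <- series@valuesB
  d <- a - b; m <- (a + b) / 2
  if (is.null(main))
    main <- sprintf("%s vs %s", series@labels[1L], series@labels[2L])
  ylab <- sprintf("Difference (%s)", series@unit)
  xlab <- sprintf("Average (%s)", series@unit)
  ylim <- range(c(d, result@loa, 0), finite = TRUE)
  graphics::plot(m, d, pch = 16, cex = 0.5, col = "grey30",
                 xlab = xlab, ylab = ylab, main = main, ylim = ylim)
  graphics::abline(h = 0, col = "blue")
  if (proportional) {
    pb <- proportionalBiasBand(series)
    graphics::polygon(c(pb$band$average, rev(pb$band$average)),
                      c(pb$band$lwr, rev(pb$band$upr)),
                      col = grDevices::adjustcolor("darkgreen", 0.15),
                      border = NA)
    graphics::lines(pb$band$average, pb$band$fit, col = "red", lwd = 2)
    graphics::lines(pb$band$average, pb$band$lwr, col = "darkgreen", lty = 3)
    graphics::lines(pb$band$average, pb$band$upr, col = "darkgreen", lty = 3)
  } else {
    shade <- function(ci) graphics::rect(graphics::par("usr")[1L], ci[1L],
                                         graphics::par("usr")[2L], ci[2L],
                                         col = grDevices::adjustcolor("darkgreen", 0.15),
                                         border = NA)
    shade(result@ciLoaLower); shade(result@ciLoaUpper)
    graphics::abline(h = result@meanDiff, col = "red", lwd = 2)
    graphics::abline(h = result@loa, col = "darkgreen", lty = 3, lwd = 2)
  }
  invisible(result)
}

#' Segmentation overlay for debugging
#'
#' Writes (or draws) the B-scan with raw detections and fitted traces
#' overlaid.
#'
#' @param image a [BScanImage-class].
#' @param bounds the matching [BoundarySet-class].
#' @param file optional PNG path.
#' @return `bounds`, invisibly.
#' @export
plotSegmentation <- function(image, bounds, file = NULL) {
  stopifnot(is(image, "BScanImage"), is(bounds, "BoundarySet"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  p <- image@pixels
  h <- nrow(p); w <- ncol(p)
  graphics::plot(NA, xlim = c(0, w - 1), ylim = c(h - 1, 0), xlab = "x (px)",
                 ylab = "y (px)", main = image@imageId, asp = 1)
  graphics::rasterImage(p / 255, 0, h - 1, w - 1, 0)
  cols <- c(epithelium = "red", endothelium = "orange",
            iris_anterior = "cyan", lens_anterior = "green")
  for (nm in names(bounds@traces)) {
    tr <- bounds@traces[[nm]]
    graphics::points(tr@x, tr@yRaw, pch = ".", col = cols[[nm]])
    xx <- seq(tr@fitDomain[1L], tr@fitDomain[2L], length.out = 200L)
    graphics::lines(xx, predictTrace(tr, xx), col = cols[[nm]], lwd = 2)
  }
  sp <- bounds@spurs
  graphics::points(c(sp@left[1L], sp@right[1L]), c(sp@left[2L], sp@right[2L]),
                   pch = 4, col = "yellow", cex = 2, lwd = 2)
  invisible(bounds)
}
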