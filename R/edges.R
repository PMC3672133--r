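#' Column-wise consecutive-run edge detection
#'
#' Scans each column downward within a search band for the first row
#' satisfying the run rule: for `direction = "open_to_tissue"`, the
#' `runLength` pixels strictly above the candidate row are all 0 and the
#' `runLength` pixels at-and-below it are all 1 (an anterior surface
#' point); for `"tissue_to_open"` the polarity is inverted (the candidate
#' is the first open-space row below tissue). The run context is read from
#' the full image; the band only restricts which candidate rows qualify.
#' Columns with no qualifying row are returned as missing; the topmost
#' qualifying row wins.
#'
#' @param binary a [BinaryImage-class].
#' @param direction `"open_to_tissue"` or `"tissue_to_open"`.
#' @param band search band of candidate rows, 0-based inclusive: either a
#'   single `c(top, bottom)` pair applied to every column, or a 2-row
#'   matrix with one column per searched column. Must span at least
#'   `2 * runLength` rows.
#' @param columns 0-based columns to search (default: all).
#' @param runLength run length of the rule (default 5).
#' @return data.frame with 0-based `x` (searched columns) and `y` (first
#'   qualifying row, NA where none).
#' @export
#' @examples
#' img <- new("BScanImage",
#'   pixels = matrix(c(rep(0, 5), rep(255, 5)), ncol = 1),
#'   scaleX = 1, scaleY = 1, imageId = "col")
#' detectEdgePoints(binarize(img, 128), "open_to_tissue", c(0, 9))
detectEdgePoints <- function(binary, direction = c("open_to_tissue",
                                                   "tissue_to_open"),
                             band = NULL, columns = NULL, runLength = 5L) {
  stopifnot(is(binary, "BinaryImage"))
  direction <- match.arg(direction)
  b <- binary@pixels
  h <- nrow(b); w <- ncol(b)
  if (is.null(columns)) columns <- 0:(w - 1L)
  if (any(columns < 0L | columns > w - 1L)) stop("columns outside image")
  nc <- length(columns)
  if (is.null(band)) band <- c(0L, h - 1L)
  if (is.matrix(band)) {
    if (nrow(band) != 2L || ncol(band) != nc)
      stop("per-column band must be a 2 x length(columns) matrix")
    top <- band[1L, ]; bot <- band[2L, ]
  } else {
    top <- rep(band[1L], nc); bot <- rep(band[2L], nc)
  }
  top <- pmax(floor(top), 0); bot <- pmin(ceiling(bot), h - 1L)
  if (any(!is.finite(top)) || any(!is.finite(bot)) || any(top > bot))
    stop("search band outside image")
  if (any(bot - top + 1L < 2L * runLength))
    stop(sprintf("search band shorter than %d px", 2L * runLength))

  sub <- b[, columns + 1L, drop = FALSE]
  ## cumulative column sums with a leading zero row: CS[k + 1, ] = rows 1..k
  CS <- rbind(0, apply(sub, 2L, cumsum))
  ## candidate rows y0 (0-based) need runLength rows above and below-incl.
  y1 <- (runLength + 1L):(h - runLength + 1L)   # 1-based candidate rows
  if (!length(y1))
    stop(sprintf("search band shorter than %d px", 2L * runLength))
  above <- CS[y1, , drop = FALSE] - CS[y1 - runLength, , drop = FALSE]
  below <- CS[y1 + runLength, , drop = FALSE] - CS[y1, , drop = FALSE]
  q <- if (direction == "open_to_tissue") {
    above == 0 & below == runLength
  } else {
    above == runLength & below == 0
  }
  y0 <- y1 - 1L                                  # 0-based candidate rows
  inBand <- outer(y0, top, ">=") & outer(y0, bot, "<=")
  q <- q & inBand
  hit <- colSums(q) > 0L
  y <- rep(NA_real_, nc)
  if (any(hit))
    y[hit] <- y0[apply(q[, hit, drop = FALSE], 2L, which.max)]
  data.frame(x = columns, y = y)
}
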