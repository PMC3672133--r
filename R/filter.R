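#' 3x3 median filter
#'
#' Classic speckle suppression step applied before threshold calculation
#' and binarization. Implemented as a fully vectorised median-of-9
#' selection network (Paeth's 19-exchange network) over edge-replicated
#' shifts of the image, so it runs in a handful of whole-matrix min/max
#' operations. `passes = 2` approximates a 5x5 filter; `passes = 0`
#' disables filtering.
#'
#' @param m numeric matrix.
#' @param passes number of 3x3 passes.
#' @return filtered matrix of the same dimensions.
#' @export
medianFilter3 <- function(m, passes = 1L) {
  stopifnot(is.matrix(m), passes >= 0L)
  h <- nrow(m); w <- ncol(m)
  for (pass in seq_len(passes)) {
    shift <- function(dy, dx)
      m[pmin(pmax(seq_len(h) + dy, 1L), h),
        pmin(pmax(seq_len(w) + dx, 1L), w), drop = FALSE]
    p <- list(shift(-1L, -1L), shift(-1L, 0L), shift(-1L, 1L),
              shift(0L, -1L), shift(0L, 0L), shift(0L, 1L),
              shift(1L, -1L), shift(1L, 0L), shift(1L, 1L))
    ops <- list(c(2L, 3L), c(5L, 6L), c(8L, 9L), c(1L, 2L), c(4L, 5L),
                c(7L, 8L), c(2L, 3L), c(5L, 6L), c(8L, 9L), c(1L, 4L),
                c(6L, 9L), c(5L, 8L), c(4L, 7L), c(2L, 5L), c(3L, 6L),
                c(5L, 8L), c(5L, 3L), c(7L, 5L), c(5L, 3L))
    for (o in ops) {
      lo <- pmin(p[[o[1L]]], p[[o[2L]]])
      p[[o[2L]]] <- pmax(p[[o[1L]]], p[[o[2L]]])
      p[[o[1L]]] <- lo
    }
    m <- p[[5L]]
  }
  m
}
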