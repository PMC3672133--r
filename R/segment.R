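#' Construct a scleral spur pair
#'
#' @param left,right (x, y) pixel coordinates, 0-based; left x < right x.
#' @param source `"observer"` for clicked landmarks, `"fixture"` for
#'   generator ground truth.
#' @return a [SpurPair-class].
#' @export
SpurPair <- function(left, right, source = "observer") {
  new("SpurPair", left = as.numeric(left), right = as.numeric(right),
      source = source)
}

#' Segmentation configuration
#'
#' Tunable parameters of the semi-automatic boundary extraction. Defaults:
#' degree-4 polynomials for the two corneal surfaces and degree-2 for iris
#' and lens; running-median window 11; outlier tolerance 3 px with one
#' refit pass; 5-px run length for the edge rule; columns within 5 px of
#' the lateral borders never scanned; corneal fits restricted to an 8-mm
#' chord centred between the spurs.
#'
#' @param degreeCornea,degreeIris,degreeLens polynomial degrees.
#' @param smoothingWindow odd running-median width (px).
#' @param outlierTol refit residual cutoff (px).
#' @param runLength consecutive-pixel run of the edge rule.
#' @param lateralMargin unscanned margin at the lateral borders (px).
#' @param cornealFitHalfChord half-width of the corneal fitting chord (mm),
#'   measured from the spur midline.
#' @param endoBandOffset `c(min, max)` search offsets below the fitted
#'   epithelium for the endothelium (px).
#' @param irisBandOffset offset below the fitted endothelium at which the
#'   iris/lens search starts (px).
#' @param irisGapTol tolerance (px) for a detection to count as lying on
#'   the iris plane.
#' @param irisJumpTol adjacent-column jump (px) that marks the pupil margin.
#' @param maxMissingRun missing columns tolerated while tracking the lens
#'   across the pupil.
#' @param lensEdgeMargin columns discarded at each pupil margin before the
#'   lens fit.
#' @param medianFilterPasses 3x3 median-filter passes applied to the scan
#'   before threshold calculation and binarization (0 disables); see
#'   [medianFilter3()].
#' @return a named list of class `segmentationConfig`.
#' @export
segmentationConfig <- function(degreeCornea = 4L, degreeIris = 2L,
                               degreeLens = 2L, smoothingWindow = 11L,
                               outlierTol = 3, runLength = 5L,
                               lateralMargin = 5L,
                               cornealFitHalfChord = 4,
                               endoBandOffset = c(6L, 70L),
                               irisBandOffset = 5L, irisGapTol = 8,
                               irisJumpTol = 6, maxMissingRun = 5L,
                               lensEdgeMargin = 2L,
                               medianFilterPasses = 1L) {
  cfg <- list(degreeCornea = degreeCornea, degreeIris = degreeIris,
              degreeLens = degreeLens, smoothingWindow = smoothingWindow,
              outlierTol = outlierTol, runLength = runLength,
              lateralMargin = lateralMargin,
              cornealFitHalfChord = cornealFitHalfChord,
              endoBandOffset = endoBandOffset,
              irisBandOffset = irisBandOffset, irisGapTol = irisGapTol,
              irisJumpTol = irisJumpTol, maxMissingRun = maxMissingRun,
              lensEdgeMargin = lensEdgeMargin,
              medianFilterPasses = medianFilterPasses)
  if (any(vapply(cfg, function(v) any(!is.finite(v)) || any(v < 0),
                 logical(1L))) ||
      any(vapply(cfg[setdiff(names(cfg), "medianFilterPasses")],
                 function(v) any(v <= 0), logical(1L))))
    stop("all segmentation settings must be positive and finite")
  structure(cfg, class = "segmentationConfig")
}

## Identify the contiguous pupil run in an iris-level detection sequence.
## y: detections (NA allowed) per consecutive column; start: index nearest
## the spur midline. Expands outward while adjacent (median-filtered)
## detections stay within jumpTol, tolerating short missing stretches.
pupilRun <- function(y, start, jumpTol, maxMissingRun) {
  n <- length(y)
  present <- which(!is.na(y))
  if (!length(present)) return(integer(0L))
  start <- present[which.min(abs(present - start))]
  ys <- y
  if (length(present) >= 5L)
    ys[present] <- stats::runmed(y[present], 5L, endrule = "median")
  expand <- function(step) {
    i <- start; last <- ys[start]; missing <- 0L; edge <- start
    repeat {
      i <- i + step
      if (i < 1L || i > n) break
      if (is.na(ys[i])) {
        missing <- missing + 1L
        if (missing > maxMissingRun) break
        next
      }
      if (abs(ys[i] - last) > jumpTol) break
      last <- ys[i]; edge <- i; missing <- 0L
    }
    edge
  }
  expand(-1L):expand(1L)
}

#' Segment one B-scan into fitted tissue boundaries
#'
#' The full semi-automatic pipeline, seeded by the two observer-marked
#' scleral spurs: a calculated threshold binarizes the scan; the
#' consecutive-run edge rule then extracts, column by column, the corneal
#' epithelium (open-to-tissue over the scanned width), the endothelium
#' (tissue-to-open in a band below the fitted epithelium), and the
#' iris/lens front (open-to-tissue below the fitted endothelium, laterally
#' restricted to the spur-to-spur range). Detections echoing the anterior
#' surface are discarded; the pupil aperture is located as the contiguous
#' central run set off from the iris plane by a depth jump, splitting the
#' deep detections into an iris trace and an anterior-lens trace. Every
#' raw point set is smoothed and polynomial-fitted ([smoothAndFit()]);
#' corneal fits use the central chord about the spur midline. Missing
#' traces are recorded as QC flags rather than errors, except for the
#' corneal surfaces, which are required.
#'
#' @param image a [BScanImage-class].
#' @param spurPair a [SpurPair-class] with both spur pixel positions, or
#'   `NULL`/non-finite coordinates for an image whose spurs could not be
#'   identified (an error, mirroring the exclusion of such scans).
#' @param config a [segmentationConfig()] list.
#' @return a [BoundarySet-class].
#' @export
#' @examples
#' ph <- renderBScan(AnteriorSegmentGeometry(), noiseFree())
#' bs <- segmentBScan(bscanImage(ph), spurs(ph))
#' bs
segmentBScan <- function(image, spurPair, config = segmentationConfig()) {
  stopifnot(is(image, "BScanImage"))
  if (is.null(spurPair) || !is(spurPair, "SpurPair") ||
      any(!is.finite(c(spurPair@left, spurPair@right))))
    stop("scleral spur not identifiable")
  p <- image@pixels
  h <- nrow(p); w <- ncol(p)
  if (spurPair@left[1L] < 0 || spurPair@right[1L] > w - 1 ||
      any(c(spurPair@left[2L], spurPair@right[2L]) < 0) ||
      any(c(spurPair@left[2L], spurPair@right[2L]) > h - 1))
    stop("scleral spurs outside image bounds")
  cfg <- config
  qc <- character(0L)

  ## speckle suppression before threshold calculation and binarization
  work <- image
  if (cfg$medianFilterPasses > 0) {
    work <- new("BScanImage",
                pixels = medianFilter3(p, cfg$medianFilterPasses),
                scaleX = image@scaleX, scaleY = image@scaleY,
                imageId = image@imageId)
  }
  thr <- computeThreshold(work)
  bin <- binarize(work, thr)

  scanCols <- cfg$lateralMargin:(w - 1L - cfg$lateralMargin)
  mid <- (spurPair@left[1L] + spurPair@right[1L]) / 2
  halfChordPx <- cfg$cornealFitHalfChord / image@scaleX
  cornealCols <- scanCols[scanCols >= mid - halfChordPx &
                          scanCols <= mid + halfChordPx]

  ## epithelium: anterior open-to-tissue over the scanned width
  epiRaw <- detectEdgePoints(bin, "open_to_tissue", band = c(0L, h - 1L),
                             columns = scanCols, runLength = cfg$runLength)
  inChord <- epiRaw$x %in% cornealCols
  epi <- smoothAndFit(epiRaw$x[inChord], epiRaw$y[inChord],
                      degree = cfg$degreeCornea,
                      smoothingWindow = cfg$smoothingWindow,
                      outlierTol = cfg$outlierTol, label = "epithelium")

  ## endothelium: tissue-to-open below the fitted epithelium
  epiFitChord <- predictTrace(epi, cornealCols)
  endoBand <- rbind(epiFitChord + cfg$endoBandOffset[1L],
                    pmin(epiFitChord + cfg$endoBandOffset[2L], h - 1L))
  endoRaw <- detectEdgePoints(bin, "tissue_to_open", band = endoBand,
                              columns = cornealCols,
                              runLength = cfg$runLength)
  endo <- smoothAndFit(endoRaw$x, endoRaw$y, degree = cfg$degreeCornea,
                       smoothingWindow = cfg$smoothingWindow,
                       outlierTol = cfg$outlierTol, label = "endothelium")
  if (min(predictTrace(endo, cornealCols) - epiFitChord) <= 0)
    qc <- c(qc, "corneal traces cross")

  ## iris/lens front: open-to-tissue below the endothelium, spur-to-spur
  irisCols <- scanCols[scanCols >= ceiling(spurPair@left[1L]) &
                       scanCols <= floor(spurPair@right[1L])]
  clampX <- pmin(pmax(irisCols, endo@fitDomain[1L]), endo@fitDomain[2L])
  bandTop <- predictTrace(endo, clampX) + cfg$irisBandOffset
  bandTop <- pmin(pmax(bandTop, 0), h - 1L - 2L * cfg$runLength)
  deepRaw <- detectEdgePoints(bin, "open_to_tissue",
                              band = rbind(bandTop, rep(h - 1L,
                                                        length(irisCols))),
                              columns = irisCols,
                              runLength = cfg$runLength)
  ## discard echoes of the anterior surface (peripheral sclera/limbus)
  epiAt <- epiRaw$y[match(deepRaw$x, epiRaw$x)]
  echo <- !is.na(deepRaw$y) & !is.na(epiAt) & abs(deepRaw$y - epiAt) <= 3
  deepY <- ifelse(echo, NA_real_, deepRaw$y)

  run <- pupilRun(deepY, start = which.min(abs(irisCols - mid)),
                  jumpTol = cfg$irisJumpTol,
                  maxMissingRun = cfg$maxMissingRun)

  traces <- list(epithelium = epi, endothelium = endo)
  if (length(run) > 0.8 * length(irisCols)) {
    qc <- c(qc, "pupil aperture not resolved")
    run <- integer(0L)
  }
  irisIdx <- setdiff(seq_along(irisCols), run)
  irisY <- deepY[irisIdx]
  if (sum(!is.na(irisY)) >= cfg$degreeIris + 6L) {
    med <- stats::median(irisY, na.rm = TRUE)
    irisY[!is.na(irisY) & abs(irisY - med) > cfg$irisGapTol] <- NA_real_
  }
  irisTrace <- tryCatch(
    smoothAndFit(irisCols[irisIdx], irisY, degree = cfg$degreeIris,
                 smoothingWindow = cfg$smoothingWindow,
                 outlierTol = cfg$outlierTol, label = "iris_anterior"),
    error = function(e) NULL)
  if (is.null(irisTrace)) qc <- c(qc, "iris trace missing")
  else traces$iris_anterior <- irisTrace

  lensTrace <- NULL
  if (length(run) > 2L * cfg$lensEdgeMargin) {
    core <- run[(cfg$lensEdgeMargin + 1L):(length(run) - cfg$lensEdgeMargin)]
    lensTrace <- tryCatch(
      smoothAndFit(irisCols[core], deepY[core], degree = cfg$degreeLens,
                   smoothingWindow = cfg$smoothingWindow,
                   outlierTol = cfg$outlierTol, label = "lens_anterior"),
      error = function(e) NULL)
  }
  if (is.null(lensTrace)) qc <- c(qc, "lens trace missing")
  else traces$lens_anterior <- lensTrace

  new("BoundarySet", traces = traces, spurs = spurPair, qcFlags = qc)
}
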