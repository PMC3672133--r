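#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param object an object of the documented class.
#' @param ... passed to methods.
#' @return the corresponding slot value (see methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(object, ...) standardGeneric("pixelMatrix"))

#' @rdname accessors
#' @export
setGeneric("pixelScale", function(object, ...) standardGeneric("pixelScale"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object, ...) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(object, ...) standardGeneric("thresholdUsed"))

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(object, ...) standardGeneric("qcFlags"))

#' @rdname accessors
#' @export
setGeneric("traces", function(object, ...) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("spurs", function(object, ...) standardGeneric("spurs"))

#' @rdname accessors
#' @export
setGeneric("bscanImage", function(object, ...) standardGeneric("bscanImage"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object, ...) standardGeneric("groundTruth"))

#' Evaluate a fitted boundary at given columns
#'
#' @param object a [BoundaryTrace-class].
#' @param x column positions (0-based pixels). Defaults to the trace's
#'   raw sample columns.
#' @return fitted row positions (pixels) at `x`.
#' @export
setGeneric("predictTrace", function(object, x, ...) standardGeneric("predictTrace"))

#' @rdname predictTrace
#' @param ... unused.
#' @export
setMethod("predictTrace", "BoundaryTrace", function(object, x, ...) {
  if (missing(x)) x <- object@x
  xc <- x - object@fitCenter
  co <- object@coefficients
  y <- rep(co[length(co)], length(x))
  if (length(co) > 1L)
    for (k in rev(seq_len(length(co) - 1L))) y <- y * xc + co[k]
  y
})

#' @rdname accessors
#' @export
setMethod("pixelMatrix", "BScanImage", function(object, ...) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelMatrix", "BinaryImage", function(object, ...) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelScale", "BScanImage", function(object, ...)
  c(x = object@scaleX, y = object@scaleY))

#' @rdname accessors
#' @export
setMethod("imageId", "BScanImage", function(object, ...) object@imageId)

#' @rdname accessors
#' @export
setMethod("imageId", "OcularBiometry", function(object, ...) object@imageId)

#' @rdname accessors
#' @export
setMethod("thresholdUsed", "BinaryImage", function(object, ...)
  object@thresholdUsed)

#' @rdname accessors
#' @export
setMethod("qcFlags", "BoundarySet", function(object, ...) object@qcFlags)

#' @rdname accessors
#' @export
setMethod("qcFlags", "OcularBiometry", function(object, ...) object@qcFlags)

#' @rdname accessors
#' @export
setMethod("traces", "BoundarySet", function(object, ...) object@traces)

#' @rdname accessors
#' @export
setMethod("spurs", "BoundarySet", function(object, ...) object@spurs)

#' @rdname accessors
#' @export
setMethod("bscanImage", "PhantomBScan", function(object, ...) object@image)

#' @rdname accessors
#' @export
setMethod("groundTruth", "PhantomBScan", function(object, ...)
  object@boundaries)

#' @rdname accessors
#' @export
setMethod("spurs", "PhantomBScan", function(object, ...) object@spurs)

setMethod("show", "BScanImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BScanImage '%s': %d x %d px (%.2f x %.2f mm), range [%d, %d]\n",
              object@imageId, d[2L], d[1L],
              d[2L] * object@scaleX, d[1L] * object@scaleY,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryImage: %d x %d px, threshold %g, %.1f%% tissue\n",
              d[2L], d[1L], object@thresholdUsed,
              100 * mean(object@pixels)))
})

setMethod("show", "BoundaryTrace", function(object) {
  cat(sprintf(
    "BoundaryTrace '%s': %d raw columns (%d detected), degree %d fit on [%g, %g]\n",
    object@label, length(object@x), sum(!is.na(object@yRaw)),
    length(object@coefficients) - 1L, object@fitDomain[1L],
    object@fitDomain[2L]))
})

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet: traces {%s}\n",
              paste(names(object@traces), collapse = ", ")))
  cat(sprintf("  spurs: left (%g, %g), right (%g, %g) [%s]\n",
              object@spurs@left[1L], object@spurs@left[2L],
              object@spurs@right[1L], object@spurs@right[2L],
              object@spurs@source))
  if (length(object@qcFlags))
    cat("  QC:", paste(object@qcFlags, collapse = "; "), "\n")
})

setMethod("show", "OcularBiometry", function(object) {
  cat(sprintf("OcularBiometry '%s':\n", object@imageId))
  cat(sprintf("  CCT %.1f um | aqueous %.3f mm | ACD %.3f mm\n",
              object@cct, object@aqueousDepth, object@acd))
  cat(sprintf("  R ant %.3f mm | R post %.3f mm | K %.2f D\n",
              object@rAnterior, object@rPosterior, object@kReading))
  if (length(object@qcFlags))
    cat("  QC:", paste(object@qcFlags, collapse = "; "), "\n")
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman agreement: %s vs %s (%s), n = %d\n",
              object@labels[1L], object@labels[2L], object@unit, object@n))
  cat(sprintf("  mean diff %.4g (SD %.4g), bias %.2f%%\n",
              object@meanDiff, object@sdDiff, object@biasPercent))
  cat(sprintf("  95%% LOA (%.4g, %.4g); CI lower (%.4g, %.4g), upper (%.4g, %.4g)\n",
              object@loa[1L], object@loa[2L],
              object@ciLoaLower[1L], object@ciLoaLower[2L],
              object@ciLoaUpper[1L], object@ciLoaUpper[2L]))
  cat(sprintf("  r = %.3f; diff-on-average slope %.4g (p = %.3g); coverage %.1f%%\n",
              object@pearsonR, object@propBiasSlope, object@pSlope,
              object@coverageWithinLoa))
})

setMethod("show", "PhantomBScan", function(object) {
  cat("PhantomBScan with analytic ground truth\n")
  show(object@image)
})

setMethod("show", "AnteriorSegmentGeometry", function(object) {
  cat(sprintf(
    "AnteriorSegmentGeometry: Ra %.2f / Rp %.2f mm, CCT %.0f um, aqueous %.2f mm\n",
    object@anteriorRadius, object@posteriorRadius, object@cct,
    object@aqueousDepth))
  cat(sprintf("  iris depth %.2f mm, pupil radius %.2f mm, lens radius %.2f mm\n",
              object@irisDepth, object@pupilRadius, object@lensRadius))
})
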