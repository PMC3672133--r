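#' @import methods
NULL

## Pixel convention used throughout the package: x = column, y = row,
## 0-based integer indices, row 0 at the top (most anterior tissue).
## Pixel centers sit at integer coordinates; matrix element [y + 1, x + 1]
## holds the intensity of pixel (x, y).

#' Ground-truth physical model of one eye's anterior segment
#'
#' Describes the anterior segment of a single eye as a small set of physical
#' quantities: two circular corneal arcs sharing the central axis, an iris
#' plane with a circular pupil aperture, an anterior lens arc, the two scleral
#' spur positions, and the tissue/background intensity contrast used when the
#' eye is rendered into a B-scan raster. Physical coordinates are in mm with
#' x = 0 on the corneal axis and y = 0 at the anterior corneal apex,
#' increasing posteriorly.
#'
#' @slot anteriorRadius anterior corneal radius of curvature (mm).
#' @slot posteriorRadius posterior corneal radius of curvature (mm).
#' @slot cct central (apex) corneal thickness (micrometres).
#' @slot aqueousDepth posterior corneal apex to anterior lens apex along the
#'   central axis (mm); the "internal" anterior chamber depth.
#' @slot lensRadius anterior lens radius of curvature (mm).
#' @slot irisDepth posterior corneal apex to the iris plane (mm).
#' @slot pupilRadius pupil aperture radius (mm).
#' @slot spurLeft,spurRight physical (x, y) positions of the two scleral
#'   spurs (mm), left x negative.
#' @slot tissueIntensity,backgroundIntensity 8-bit intensities (0-255) of
#'   tissue and aqueous/air in the noise-free rendering.
#' @seealso [AnteriorSegmentGeometry()] for the constructor with
#'   population-typical defaults, [renderBScan()].
#' @export
setClass("AnteriorSegmentGeometry",
  slots = c(
    anteriorRadius = "numeric",
    posteriorRadius = "numeric",
    cct = "numeric",
    aqueousDepth = "numeric",
    lensRadius = "numeric",
    irisDepth = "numeric",
    pupilRadius = "numeric",
    spurLeft = "numeric",
    spurRight = "numeric",
    tissueIntensity = "numeric",
    backgroundIntensity = "numeric"
  )
)

setValidity("AnteriorSegmentGeometry", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  for (nm in c("anteriorRadius", "posteriorRadius", "cct", "aqueousDepth",
               "lensRadius", "irisDepth", "pupilRadius")) {
    v <- slot(object, nm)
    if (!sc(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", nm))
  }
  if (sc(object@irisDepth) && sc(object@aqueousDepth) &&
      object@irisDepth > object@aqueousDepth)
    msg <- c(msg, "'irisDepth' must not exceed 'aqueousDepth'")
  if (length(object@spurLeft) != 2L || length(object@spurRight) != 2L)
    msg <- c(msg, "spur positions must be (x, y) pairs")
  else if (object@spurLeft[1L] >= object@spurRight[1L])
    msg <- c(msg, "spurLeft x must be less than spurRight x")
  ti <- object@tissueIntensity; bi <- object@backgroundIntensity
  if (!sc(ti) || !sc(bi) || ti < 0 || ti > 255 || bi < 0 || bi > 255)
    msg <- c(msg, "intensities must be single values in [0, 255]")
  else if (ti <= bi)
    msg <- c(msg, "tissueIntensity must exceed backgroundIntensity")
  if (length(msg)) msg else TRUE
})

#' Speckle/noise corruption model for rendered B-scans
#'
#' Multiplicative gamma speckle (mean 1, shape `speckleShape`), then additive
#' Gaussian read noise, then optional salt-and-pepper dropouts, clipped to
#' the 8-bit range. `speckleShape = 0` and `additiveSd = 0` disable the
#' respective component.
#'
#' @slot speckleShape gamma shape of the multiplicative speckle field
#'   (0 disables; larger is milder: relative SD is `1/sqrt(shape)`).
#' @slot additiveSd SD of additive Gaussian noise, intensity units.
#' @slot saltPepperFraction fraction of pixels replaced by 0 or 255.
#' @export
setClass("NoiseModel",
  slots = c(
    speckleShape = "numeric",
    additiveSd = "numeric",
    saltPepperFraction = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@speckleShape < 0) msg <- c(msg, "speckleShape must be >= 0")
  if (object@additiveSd < 0) msg <- c(msg, "additiveSd must be >= 0")
  if (object@saltPepperFraction < 0 || object@saltPepperFraction >= 1)
    msg <- c(msg, "saltPepperFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated paired-measurement cohort
#'
#' Generating model for two instruments measuring the same underlying
#' quantity on `n` eyes: truth is Normal(`trueMean`, `trueSd`); modality A
#' reads truth plus Normal(0, `noiseSdEach`); modality B reads truth plus
#' `biasIntercept + biasSlope * truth` plus independent Normal(0,
#' `noiseSdEach`). `biasSlope = 0` yields a constant between-method bias,
#' `biasSlope != 0` a proportional one.
#'
#' @slot n number of paired measurements (>= 2).
#' @slot trueMean,trueSd mean and SD of the underlying true values.
#' @slot biasIntercept,biasSlope systematic bias of modality B against truth.
#' @slot noiseSdEach measurement noise SD applied independently to each
#'   modality.
#' @slot seed integer RNG seed making the cohort reproducible.
#' @export
setClass("PairedCohortSpec",
  slots = c(
    n = "numeric",
    trueMean = "numeric",
    trueSd = "numeric",
    biasIntercept = "numeric",
    biasSlope = "numeric",
    noiseSdEach = "numeric",
    seed = "numeric"
  )
)

setValidity("PairedCohortSpec", function(object) {
  msg <- character()
  if (object@n < 2) msg <- c(msg, "n must be >= 2")
  if (object@trueSd < 0) msg <- c(msg, "trueSd must be >= 0")
  if (object@noiseSdEach < 0) msg <- c(msg, "noiseSdEach must be >= 0")
  if (length(msg)) msg else TRUE
})

#' 8-bit grayscale B-scan raster with physical pixel scale
#'
#' @slot pixels integer-valued matrix of intensities in \[0, 255\];
#'   `pixels[y + 1, x + 1]` is pixel (column x, row y), 0-based, row 0 at top.
#' @slot scaleX,scaleY physical size of one pixel (mm) laterally and axially.
#' @slot imageId identifier carried through to all per-image outputs.
#' @export
setClass("BScanImage",
  slots = c(
    pixels = "matrix",
    scaleX = "numeric",
    scaleY = "numeric",
    imageId = "character"
  )
)

setValidity("BScanImage", function(object) {
  p <- object@pixels
  msg <- character()
  if (!is.numeric(p)) msg <- c(msg, "pixels must be numeric")
  else {
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      msg <- c(msg, "intensities must lie in [0, 255]")
    if (any(p != round(p)))
      msg <- c(msg, "intensities must be integer-valued (8-bit)")
  }
  if (object@scaleX <= 0 || object@scaleY <= 0)
    msg <- c(msg, "pixel scales must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binary (tissue / open-space) copy of a B-scan
#'
#' @slot pixels matrix of 1s (tissue) and 0s (open space).
#' @slot thresholdUsed the intensity threshold that produced it.
#' @export
setClass("BinaryImage",
  slots = c(pixels = "matrix", thresholdUsed = "numeric")
)

setValidity("BinaryImage", function(object) {
  if (!all(object@pixels %in% c(0, 1)))
    return("binary pixels must be 0 or 1 only")
  TRUE
})

#' Observer-marked scleral spur pair
#'
#' The two scleral spur pixel positions that seed the semi-automatic
#' analysis; the only manual input of the pipeline.
#'
#' @slot left,right (x, y) pixel coordinates, 0-based; left x < right x.
#' @slot source `"observer"` for clicked landmarks, `"fixture"` for
#'   generator-provided ground truth.
#' @export
setClass("SpurPair",
  slots = c(left = "numeric", right = "numeric", source = "character")
)

setValidity("SpurPair", function(object) {
  msg <- character()
  if (length(object@left) != 2L || length(object@right) != 2L)
    msg <- c(msg, "spur coordinates must be (x, y) pairs")
  else if (!all(is.finite(c(object@left, object@right))))
    msg <- c(msg, "spur coordinates must be finite")
  else if (object@left[1L] >= object@right[1L])
    msg <- c(msg, "left spur must lie left of right spur")
  if (!object@source %in% c("observer", "fixture"))
    msg <- c(msg, "source must be 'observer' or 'fixture'")
  if (length(msg)) msg else TRUE
})

#' One detected-and-fitted tissue boundary
#'
#' Raw per-column edge samples (missing columns allowed) together with the
#' smoothed polynomial fit. The polynomial is parameterised in centred
#' column coordinates for conditioning: `y(x) = sum(coefficients[k+1] *
#' (x - fitCenter)^k)`.
#'
#' @slot x 0-based column positions of the raw samples, strictly increasing.
#' @slot yRaw raw detected row per column (NA where the edge rule found
#'   no qualifying row).
#' @slot coefficients polynomial coefficients, ascending powers of
#'   `(x - fitCenter)`.
#' @slot fitCenter centring constant used for the fit (pixels).
#' @slot fitDomain inclusive column range over which the fit is valid.
#' @slot label one of `"epithelium"`, `"endothelium"`, `"iris_anterior"`,
#'   `"lens_anterior"`.
#' @export
setClass("BoundaryTrace",
  slots = c(
    x = "numeric",
    yRaw = "numeric",
    coefficients = "numeric",
    fitCenter = "numeric",
    fitDomain = "numeric",
    label = "character"
  )
)

setValidity("BoundaryTrace", function(object) {
  msg <- character()
  if (length(object@x) != length(object@yRaw))
    msg <- c(msg, "x and yRaw must have equal length")
  if (length(object@x) > 1L && any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (length(object@fitDomain) != 2L || object@fitDomain[1L] > object@fitDomain[2L])
    msg <- c(msg, "fitDomain must be an increasing (lo, hi) pair")
  if (!object@label %in% c("epithelium", "endothelium", "iris_anterior",
                           "lens_anterior"))
    msg <- c(msg, "unknown trace label")
  if (length(msg)) msg else TRUE
})

#' Full segmentation result for one B-scan
#'
#' @slot traces named list of [BoundaryTrace-class] objects (epithelium,
#'   endothelium, iris_anterior; lens_anterior when the pupil aperture is
#'   resolvable).
#' @slot spurs the seeding [SpurPair-class].
#' @slot qcFlags character vector of quality-control annotations.
#' @export
setClass("BoundarySet",
  slots = c(traces = "list", spurs = "SpurPair", qcFlags = "character")
)

setValidity("BoundarySet", function(object) {
  if (length(object@traces) &&
      (is.null(names(object@traces)) || any(!nzchar(names(object@traces)))))
    return("traces must be a named list")
  ok <- vapply(object@traces, is, logical(1L), class2 = "BoundaryTrace")
  if (!all(ok)) return("all traces must be BoundaryTrace objects")
  TRUE
})

#' Derived anterior-segment biometry for one eye
#'
#' @slot imageId image identifier.
#' @slot cct central corneal thickness (micrometres).
#' @slot aqueousDepth internal anterior chamber depth (mm), posterior cornea
#'   to anterior lens at the apex column.
#' @slot acd anterior chamber depth (mm), `aqueousDepth + cct/1000` by
#'   construction, matching optical-biometer convention.
#' @slot rAnterior,rPosterior corneal radii of curvature (mm).
#' @slot kReading keratometry (diopters) from the anterior radius.
#' @slot apexX apex column (pixels).
#' @slot qcFlags quality-control annotations.
#' @export
setClass("OcularBiometry",
  slots = c(
    imageId = "character",
    cct = "numeric",
    aqueousDepth = "numeric",
    acd = "numeric",
    rAnterior = "numeric",
    rPosterior = "numeric",
    kReading = "numeric",
    apexX = "numeric",
    qcFlags = "character"
  )
)

setValidity("OcularBiometry", function(object) {
  msg <- character()
  if (is.finite(object@cct) && object@cct <= 0)
    msg <- c(msg, "cct must be positive")
  if (is.finite(object@acd) && is.finite(object@aqueousDepth) &&
      is.finite(object@cct) &&
      abs(object@acd - (object@aqueousDepth + object@cct / 1000)) > 1e-9)
    msg <- c(msg, "acd must equal aqueousDepth + cct/1000")
  if (length(msg)) msg else TRUE
})

#' Bland-Altman agreement summary for one paired series
#'
#' All quantities use the difference direction a - b (device minus
#' reference).
#'
#' @slot n number of pairs.
#' @slot meanDiff,sdDiff mean and SD of the paired differences.
#' @slot grandMean mean of the per-pair averages.
#' @slot biasPercent 100 * meanDiff / grandMean.
#' @slot loa 95% limits of agreement, `meanDiff +/- 1.96 * sdDiff`.
#' @slot ciLoaLower,ciLoaUpper 95% confidence intervals of the two limits.
#' @slot pPairedT two-sided paired t-test p-value.
#' @slot pearsonR Pearson correlation between the two modality vectors.
#' @slot propBiasSlope,propBiasIntercept,pSlope OLS of difference on average
#'   (proportional-bias check) and the two-sided slope p-value.
#' @slot coverageWithinLoa percentage of differences inside the limits.
#' @slot labels,unit descriptive labels of the two modalities and the unit.
#' @slot qcFlags degeneracy annotations (e.g. identical constant series).
#' @export
setClass("BlandAltmanResult",
  slots = c(
    n = "numeric",
    meanDiff = "numeric",
    sdDiff = "numeric",
    grandMean = "numeric",
    biasPercent = "numeric",
    loa = "numeric",
    ciLoaLower = "numeric",
    ciLoaUpper = "numeric",
    pPairedT = "numeric",
    pearsonR = "numeric",
    propBiasSlope = "numeric",
    propBiasIntercept = "numeric",
    pSlope = "numeric",
    coverageWithinLoa = "numeric",
    labels = "character",
    unit = "character",
    qcFlags = "character"
  )
)

setValidity("BlandAltmanResult", function(object) {
  msg <- character()
  if (length(object@loa) == 2L && all(is.finite(object@loa)) &&
      is.finite(object@sdDiff)) {
    if (abs(diff(object@loa) - 2 * 1.96 * object@sdDiff) > 1e-8 *
        max(1, object@sdDiff))
      msg <- c(msg, "LOA width must equal 2 * 1.96 * sdDiff")
    if (abs(mean(object@loa) - object@meanDiff) > 1e-8 *
        max(1, abs(object@meanDiff)))
      msg <- c(msg, "LOA midpoint must equal meanDiff")
  }
  if (is.finite(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    msg <- c(msg, "pearsonR must lie in [-1, 1]")
  if (is.finite(object@coverageWithinLoa) &&
      (object@coverageWithinLoa < 0 || object@coverageWithinLoa > 100))
    msg <- c(msg, "coverageWithinLoa must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Aligned paired-measurement series
#'
#' @slot valuesA,valuesB aligned measurements of the same eyes by two
#'   modalities; by convention A is the device under evaluation and B the
#'   reference instrument.
#' @slot labels names of the two modalities.
#' @slot unit measurement unit.
#' @export
setClass("PairedSeries",
  slots = c(valuesA = "numeric", valuesB = "numeric",
            labels = "character", unit = "character")
)

setValidity("PairedSeries", function(object) {
  msg <- character()
  if (length(object@valuesA) != length(object@valuesB))
    msg <- c(msg, "the two series must have equal length")
  if (length(object@valuesA) < 3L)
    msg <- c(msg, "need at least 3 pairs")
  if (anyNA(object@valuesA) || anyNA(object@valuesB))
    msg <- c(msg, "no missing entries allowed after pairing")
  if (length(msg)) msg else TRUE
})

#' Rendered phantom with analytic ground truth
#'
#' @slot image the rendered [BScanImage-class].
#' @slot boundaries data.frame with columns `x`, `yAnterior`, `yPosterior`,
#'   `yIris`, `yLens`: exact analytic boundary rows per column, pixel
#'   coordinates, NA where a surface is absent from that column.
#' @slot spurs ground-truth spur pixel positions (source `"fixture"`).
#' @slot geometry the generating [AnteriorSegmentGeometry-class].
#' @export
setClass("PhantomBScan",
  slots = c(
    image = "BScanImage",
    boundaries = "data.frame",
    spurs = "SpurPair",
    geometry = "AnteriorSegmentGeometry"
  )
)
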