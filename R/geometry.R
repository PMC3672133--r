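#' Construct an anterior-segment geometry
#'
#' Defaults describe a population-typical adult eye consistent with the
#' cohort this pipeline is calibrated for: anterior corneal radius 7.2 mm
#' (K about 46.9 D under the 1.3375 keratometric convention), apex corneal
#' thickness 560 um, aqueous depth 2.73 mm so that ACD = aqueous + CCT is
#' 3.29 mm. The iris plane sits slightly anterior to the lens apex so the
#' pupil aperture is resolvable in the rendered scan; scleral spurs sit at
#' +/- 6 mm laterally, embedded just below the anterior (scleral) surface.
#'
#' @param anteriorRadius,posteriorRadius corneal radii of curvature (mm).
#' @param cct central corneal thickness (micrometres).
#' @param aqueousDepth posterior cornea to anterior lens along the axis (mm).
#' @param lensRadius anterior lens radius of curvature (mm).
#' @param irisDepth posterior corneal apex to iris plane (mm); defaults to
#'   0.23 mm anterior to the lens apex.
#' @param pupilRadius pupil aperture radius (mm).
#' @param spurX lateral distance of each scleral spur from the axis (mm);
#'   used when `spurLeft`/`spurRight` are not given.
#' @param spurLeft,spurRight explicit (x, y) spur positions (mm, apex
#'   origin). Default: on the anterior scleral surface at `+/- spurX`,
#'   0.1 mm deep.
#' @param tissueIntensity,backgroundIntensity rendering intensities (0-255).
#' @return an [AnteriorSegmentGeometry-class] object.
#' @export
#' @examples
#' AnteriorSegmentGeometry()
AnteriorSegmentGeometry <- function(anteriorRadius = 7.2,
                                    posteriorRadius = 0.89 * anteriorRadius,
                                    cct = 560,
                                    aqueousDepth = 2.73,
                                    lensRadius = 10,
                                    irisDepth = aqueousDepth - 0.23,
                                    pupilRadius = 2,
                                    spurX = 6,
                                    spurLeft = NULL,
                                    spurRight = NULL,
                                    tissueIntensity = 180,
                                    backgroundIntensity = 20) {
  if (is.null(spurLeft) || is.null(spurRight)) {
    if (spurX >= anteriorRadius)
      stop("spurX must be inside the anterior arc's lateral extent")
    ySpur <- anteriorRadius - sqrt(anteriorRadius^2 - spurX^2) + 0.1
    spurLeft <- c(-spurX, ySpur)
    spurRight <- c(spurX, ySpur)
  }
  new("AnteriorSegmentGeometry",
      anteriorRadius = anteriorRadius, posteriorRadius = posteriorRadius,
      cct = cct, aqueousDepth = aqueousDepth, lensRadius = lensRadius,
      irisDepth = irisDepth, pupilRadius = pupilRadius,
      spurLeft = spurLeft, spurRight = spurRight,
      tissueIntensity = tissueIntensity,
      backgroundIntensity = backgroundIntensity)
}

#' Construct a noise model
#'
#' Default corruption is mild OCT-like speckle: multiplicative gamma
#' speckle with shape 4 (relative SD 0.5) followed by additive Gaussian
#' noise with SD 8 intensity units; no salt-and-pepper dropouts.
#'
#' @param speckleShape gamma shape (0 disables speckle).
#' @param additiveSd additive Gaussian SD, intensity units.
#' @param saltPepperFraction fraction of pixels replaced by 0 or 255.
#' @return a [NoiseModel-class] object.
#' @export
#' @examples
#' NoiseModel()        # default speckle
#' noiseFree()
NoiseModel <- function(speckleShape = 4, additiveSd = 8,
                       saltPepperFraction = 0) {
  new("NoiseModel", speckleShape = speckleShape, additiveSd = additiveSd,
      saltPepperFraction = saltPepperFraction)
}

#' @rdname NoiseModel
#' @export
noiseFree <- function() NoiseModel(0, 0, 0)

#' Sample random anterior-segment geometries
#'
#' Draws geometries uniformly over clinically plausible ranges: CCT
#' 480-640 um, ACD (aqueous + CCT) 2.6-4.0 mm, anterior radius 6.5-8.5 mm,
#' posterior radius 0.89 x anterior. Iris depth tracks the aqueous depth at
#' a fixed 0.23 mm offset so the pupil aperture stays resolvable.
#'
#' @param n number of geometries.
#' @param seed RNG seed.
#' @param cctRange,acdRange,radiusRange sampling ranges (um, mm, mm).
#' @return a list of [AnteriorSegmentGeometry-class] objects.
#' @export
sampleGeometries <- function(n, seed = 1,
                             cctRange = c(480, 640),
                             acdRange = c(2.6, 4.0),
                             radiusRange = c(6.5, 8.5)) {
  stopifnot(isCount(n))
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      cct <- stats::runif(1, cctRange[1L], cctRange[2L])
      acd <- stats::runif(1, acdRange[1L], acdRange[2L])
      ra <- stats::runif(1, radiusRange[1L], radiusRange[2L])
      AnteriorSegmentGeometry(anteriorRadius = ra, cct = cct,
                              aqueousDepth = acd - cct / 1000)
    })
  })
}
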