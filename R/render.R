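## Phantom renderer. Physical frame: x = 0 on the corneal axis (mm), depth
## d = 0 at the anterior corneal apex, increasing posteriorly. The raster
## places the apex `apexOffset` mm below the top edge. Tissue regions are
## half-open in depth ([upper, lower) boundary), so a surface crossing an
## integer row puts that row's pixel in the region below the surface.

## Analytic surface depths (mm) per lateral position; NA outside support.
arcDepth <- function(x, radius, apexDepth) {
  s <- radius^2 - x^2
  d <- rep(NA_real_, length(x))
  ok <- s >= 0
  d[ok] <- apexDepth + radius - sqrt(s[ok])
  d
}

#' Render a phantom B-scan with analytic ground truth
#'
#' Rasterises an [AnteriorSegmentGeometry-class] into an 8-bit grayscale
#' B-scan: cornea between the two arcs, scleral shell continuing the
#' anterior arc beyond the spur positions, iris plane with pupil aperture,
#' anterior lens cap; tissue takes `tissueIntensity`, aqueous/air takes
#' `backgroundIntensity`; then the noise model is applied. The exact
#' analytic boundary curves, sampled at every column in pixel coordinates,
#' are returned alongside as ground truth. Rendering is deterministic given
#' `seed`, and seed-independent when the noise model is fully disabled.
#'
#' @param geometry an [AnteriorSegmentGeometry-class].
#' @param noise a [NoiseModel-class]; `noiseFree()` disables corruption.
#' @param width,height raster size in pixels (columns x rows; both >= 50).
#' @param fov physical field of view `c(lateral, axial)` in mm. The default
#'   16 x 6 mm over 600 x 300 px gives 26.67 um lateral and 20 um axial
#'   pixels.
#' @param apexOffset depth of the corneal apex below the top edge (mm).
#' @param lateralShift lateral displacement of the whole eye from the
#'   raster centre (mm, positive = toward larger x).
#' @param seed RNG seed for the noise field.
#' @param imageId identifier stored in the image.
#' @return a [PhantomBScan-class]: image, per-column ground-truth
#'   boundaries (`x`, `yAnterior`, `yPosterior`, `yIris`, `yLens`, 0-based
#'   pixels), and ground-truth spur pixel positions.
#' @export
#' @examples
#' ph <- renderBScan(AnteriorSegmentGeometry(), noiseFree())
#' bscanImage(ph)
renderBScan <- function(geometry, noise = NoiseModel(),
                        width = 600, height = 300, fov = c(16, 6),
                        apexOffset = 1, lateralShift = 0, seed = 1,
                        imageId = "phantom") {
  stopifnot(is(geometry, "AnteriorSegmentGeometry"), is(noise, "NoiseModel"))
  validObject(geometry); validObject(noise)
  if (width < 50 || height < 50) stop("width and height must be >= 50")
  if (length(fov) != 2L || any(fov <= 0)) stop("fov must be two positive extents")
  scaleX <- fov[1L] / width
  scaleY <- fov[2L] / height
  xs <- (seq_len(width) - 1 - (width - 1) / 2) * scaleX - lateralShift
  ds <- (seq_len(height) - 1) * scaleY - apexOffset        # depth per row

  g <- geometry
  cctmm <- g@cct / 1000
  dAnt <- arcDepth(xs, g@anteriorRadius, 0)
  dPost <- arcDepth(xs, g@posteriorRadius, cctmm)
  dIris <- cctmm + g@irisDepth
  dLens <- arcDepth(xs, g@lensRadius, cctmm + g@aqueousDepth)
  spurX <- g@spurRight[1L]
  irisThick <- 0.35
  lensThick <- 1.5
  lensHalfWidth <- 4.5
  maxDepth <- fov[2L] - apexOffset

  if (apexOffset <= 0 || apexOffset >= fov[2L])
    stop("anterior cornea outside the field of view")
  if (cctmm + g@aqueousDepth >= maxDepth)
    stop("anterior lens outside the field of view")
  if (dIris >= maxDepth)
    stop("iris plane outside the field of view")
  if (abs(g@spurLeft[1L] + lateralShift) >= fov[1L] / 2 ||
      spurX + abs(lateralShift) >= fov[1L] / 2 ||
      max(g@spurLeft[2L], g@spurRight[2L]) >= maxDepth)
    stop("scleral spur outside the field of view")

  ## region masks, height x width, pixel centre test, half-open in depth
  D <- matrix(ds, nrow = height, ncol = width)
  rowGE <- function(curve) D >= matrix(curve, height, width, byrow = TRUE)
  rowLT <- function(curve) D < matrix(curve, height, width, byrow = TRUE)
  central <- matrix(abs(xs) < spurX, height, width, byrow = TRUE)
  antDef <- matrix(!is.na(dAnt), height, width, byrow = TRUE)
  postDef <- matrix(!is.na(dPost), height, width, byrow = TRUE)
  dAnt0 <- ifelse(is.na(dAnt), Inf, dAnt)
  dPost0 <- ifelse(is.na(dPost), -Inf, dPost)
  dLens0 <- ifelse(is.na(dLens), Inf, dLens)

  cornea <- central & antDef & postDef & rowGE(dAnt0) & rowLT(dPost0)
  sclera <- antDef & rowGE(dAnt0) & (!central | !postDef)
  irisCols <- abs(xs) >= g@pupilRadius & abs(xs) < spurX &
    (is.na(dPost) | dIris >= dPost)
  iris <- matrix(irisCols, height, width, byrow = TRUE) &
    D >= dIris & D < dIris + irisThick
  lens <- matrix(abs(xs) <= lensHalfWidth, height, width, byrow = TRUE) &
    rowGE(dLens0) & rowLT(dLens0 + lensThick)

  tissue <- cornea | sclera | iris | lens
  img <- matrix(g@backgroundIntensity, height, width)
  img[tissue] <- g@tissueIntensity
  img <- applyNoise(img, noise, seed)

  image <- new("BScanImage", pixels = img, scaleX = scaleX, scaleY = scaleY,
               imageId = imageId)

  toRow <- function(depth) (depth + apexOffset) / scaleY
  inImage <- function(y) ifelse(!is.na(y) & y >= 0 & y <= height - 1, y, NA_real_)
  boundaries <- data.frame(
    x = seq_len(width) - 1,
    yAnterior = inImage(toRow(dAnt)),
    yPosterior = inImage(ifelse(abs(xs) < spurX, toRow(dPost), NA_real_)),
    yIris = inImage(ifelse(irisCols & !is.na(dPost) & dIris > dPost,
                           toRow(dIris), NA_real_)),
    yLens = inImage(ifelse(abs(xs) < g@pupilRadius, toRow(dLens), NA_real_))
  )
  spurPx <- new("SpurPair",
                left = c((g@spurLeft[1L] + lateralShift) / scaleX +
                           (width - 1) / 2, toRow(g@spurLeft[2L])),
                right = c((g@spurRight[1L] + lateralShift) / scaleX +
                            (width - 1) / 2, toRow(g@spurRight[2L])),
                source = "fixture")
  new("PhantomBScan", image = image, boundaries = boundaries,
      spurs = spurPx, geometry = geometry)
}

## Apply the noise model; consumes RNG only when some component is active.
applyNoise <- function(img, noise, seed) {
  active <- noise@speckleShape > 0 || noise@additiveSd > 0 ||
    noise@saltPepperFraction > 0
  if (!active) return(clip8bit(img))
  withSeed(seed, {
    if (noise@speckleShape > 0)
      img <- img * matrix(stats::rgamma(length(img), shape = noise@speckleShape,
                                        rate = noise@speckleShape),
                          nrow(img), ncol(img))
    if (noise@additiveSd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise@additiveSd),
                          nrow(img), ncol(img))
    if (noise@saltPepperFraction > 0) {
      k <- round(noise@saltPepperFraction * length(img))
      if (k > 0) {
        idx <- sample.int(length(img), k)
        img[idx] <- sample(c(0, 255), k, replace = TRUE)
      }
    }
    clip8bit(img)
  })
}
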