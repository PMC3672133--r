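#' Generate a phantom image cohort with annotations and ground truth
#'
#' Renders `n` phantom B-scans from randomly sampled geometries, writes the
#' images, a scleral-spur annotation table, and the true per-eye biometry.
#' A configurable fraction of images is flagged spur-not-visible (their
#' spur coordinates withheld), emulating scans that must be excluded from
#' semi-automatic analysis.
#'
#' Annotation CSV columns: `image_id`, `spur_left_x`, `spur_left_y`,
#' `spur_right_x`, `spur_right_y`, `spur_visible` (0/1); pixel units,
#' 0-based. Ground-truth CSV columns: `image_id`, `cct_um`, `aqueous_mm`,
#' `acd_mm`, `r_ant_mm`, `r_post_mm`, `k_ant_d`.
#'
#' @param n number of eyes (>= 1).
#' @param outDir output directory (created if needed).
#' @param seed RNG seed governing geometry sampling, noise fields and
#'   spur-visibility flags.
#' @param noise a [NoiseModel-class] applied to every image.
#' @param spurMissingFraction probability that an image's spurs are
#'   unidentifiable.
#' @param format image format: `"png"`, `"tiff"` or `"pgm"`.
#' @param width,height,fov,apexOffset raster parameters of [renderBScan()].
#' @param cctRange,acdRange,radiusRange geometry sampling ranges of
#'   [sampleGeometries()].
#' @param keratometricIndex index used for the ground-truth K column.
#' @return invisibly, a list with `images` (paths), `annotations` and
#'   `truth` (data.frames, also written as CSV), and the CSV paths.
#' @export
makeCohortImages <- function(n, outDir, seed = 1, noise = NoiseModel(),
                             spurMissingFraction = 0, format = "png",
                             width = 600, height = 300, fov = c(16, 6),
                             apexOffset = 1,
                             cctRange = c(480, 640), acdRange = c(2.6, 4.0),
                             radiusRange = c(6.5, 8.5),
                             keratometricIndex = 1.3375) {
  stopifnot(isCount(n))
  if (spurMissingFraction < 0 || spurMissingFraction >= 1)
    stop("spurMissingFraction must be in [0, 1)")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  geoms <- sampleGeometries(n, seed = seed, cctRange = cctRange,
                            acdRange = acdRange, radiusRange = radiusRange)
  visible <- withSeed(seed + 1L, stats::runif(n) >= spurMissingFraction)

  ids <- sprintf("eye%04d", seq_len(n))
  paths <- file.path(outDir, paste0(ids, ".", format))
  ann <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    ph <- renderBScan(g, noise = noise, width = width, height = height,
                      fov = fov, apexOffset = apexOffset,
                      seed = seed + 1000L + i, imageId = ids[i])
    writeBScan(ph@image, paths[i])
    sp <- ph@spurs
    ann[[i]] <- data.frame(
      image_id = ids[i],
      spur_left_x = if (visible[i]) round(sp@left[1L], 2) else NA_real_,
      spur_left_y = if (visible[i]) round(sp@left[2L], 2) else NA_real_,
      spur_right_x = if (visible[i]) round(sp@right[1L], 2) else NA_real_,
      spur_right_y = if (visible[i]) round(sp@right[2L], 2) else NA_real_,
      spur_visible = as.integer(visible[i]))
    truth[[i]] <- data.frame(
      image_id = ids[i],
      cct_um = g@cct,
      aqueous_mm = g@aqueousDepth,
      acd_mm = g@aqueousDepth + g@cct / 1000,
      r_ant_mm = g@anteriorRadius,
      r_post_mm = g@posteriorRadius,
      k_ant_d = keratometry(g@anteriorRadius, keratometricIndex))
  }
  annotations <- do.call(rbind, ann)
  truthTab <- do.call(rbind, truth)
  annPath <- file.path(outDir, "annotations.csv")
  truthPath <- file.path(outDir, "ground_truth.csv")
  utils::write.csv(annotations, annPath, row.names = FALSE)
  utils::write.csv(truthTab, truthPath, row.names = FALSE)
  invisible(list(images = paths, annotations = annotations,
                 truth = truthTab, annotationsPath = annPath,
                 truthPath = truthPath))
}
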