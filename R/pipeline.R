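#' Convert a biometry object list to a table
#'
#' @param biometries list of [OcularBiometry-class] objects.
#' @return data.frame with columns `image_id`, `cct_um`, `aqueous_mm`,
#'   `acd_mm`, `r_ant_mm`, `r_post_mm`, `k_d`, `qc_flags`.
#' @export
biometryTable <- function(biometries) {
  do.call(rbind, lapply(biometries, function(b) {
    data.frame(image_id = b@imageId, cct_um = b@cct,
               aqueous_mm = b@aqueousDepth, acd_mm = b@acd,
               r_ant_mm = b@rAnterior, r_post_mm = b@rPosterior,
               k_d = b@kReading,
               qc_flags = paste(b@qcFlags, collapse = "; "))
  }))
}

#' Segment and measure a cohort of B-scan images
#'
#' Runs [segmentBScan()] and [measureBiometry()] over every annotated
#' image. Images whose annotation has `spur_visible = 0` (or missing spur
#' coordinates) are excluded and accounted for, mirroring the handling of
#' scans without identifiable scleral spurs.
#'
#' @param imagePaths character vector of image files.
#' @param annotations data.frame in the annotation-CSV layout of
#'   [makeCohortImages()] (matched to images by `image_id` = file base
#'   name).
#' @param scaleX,scaleY physical pixel sizes (mm per pixel).
#' @param config a [segmentationConfig()].
#' @param zone,index curvature zone (mm) and keratometric index.
#' @return list with `biometry` (data.frame, one row per analysed image)
#'   and `exclusions` (data.frame `image_id`, `reason`).
#' @export
analyzeCohort <- function(imagePaths, annotations, scaleX = 16 / 600,
                          scaleY = 6 / 300, config = segmentationConfig(),
                          zone = NULL, index = 1.3375) {
  ids <- tools::file_path_sans_ext(basename(imagePaths))
  rows <- list(); excl <- list()
  for (i in seq_along(imagePaths)) {
    id <- ids[i]
    ann <- annotations[annotations$image_id == id, , drop = FALSE]
    res <- tryCatch({
      if (nrow(ann) != 1L) stop("annotation row missing")
      if (!ann$spur_visible[1L] ||
          anyNA(c(ann$spur_left_x, ann$spur_left_y,
                  ann$spur_right_x, ann$spur_right_y)))
        stop("scleral spur not identifiable")
      img <- readBScan(imagePaths[i], scaleX = scaleX, scaleY = scaleY,
                       imageId = id)
      sp <- SpurPair(c(ann$spur_left_x, ann$spur_left_y),
                     c(ann$spur_right_x, ann$spur_right_y),
                     source = "observer")
      bounds <- segmentBScan(img, sp, config = config)
      measureBiometry(bounds, scaleX = scaleX, scaleY = scaleY,
                      zone = zone, index = index, imageId = id)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) excl[[length(excl) + 1L]] <-
        data.frame(image_id = id, reason = res)
    else rows[[length(rows) + 1L]] <- biometryTable(list(res))
  }
  list(biometry = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(image_id = character(0L), reason = character(0L)))
}

#' Agreement-table row(s) in reporting layout
#'
#' Formats one or more [BlandAltmanResult-class] objects as the standard
#' printed comparison table: grand mean, mean (SD) difference, bias %,
#' paired-t p, 95% LOA and the 95% CIs of both limits. Rounding is half
#' away from zero at 2 decimals.
#'
#' @param results list of [BlandAltmanResult-class] (or a single one).
#' @param digits decimals for the rounded columns.
#' @return data.frame, one row per comparison.
#' @export
agreementTable <- function(results, digits = 2L) {
  if (is(results, "BlandAltmanResult")) results <- list(results)
  r2 <- function(x) roundHalfAway(x, digits)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      parameter = paste(r@labels, collapse = " vs "),
      unit = r@unit, n = r@n,
      mean = r2(r@grandMean),
      diff_mean = r2(r@meanDiff), diff_sd = r2(r@sdDiff),
      bias_percent = r2(r@biasPercent),
      p_value = signif(r@pPairedT, 3L),
      loa_lower = r2(r@loa[1L]), loa_upper = r2(r@loa[2L]),
      ci_loa_lower_lo = r2(r@ciLoaLower[1L]),
      ci_loa_lower_hi = r2(r@ciLoaLower[2L]),
      ci_loa_upper_lo = r2(r@ciLoaUpper[1L]),
      ci_loa_upper_hi = r2(r@ciLoaUpper[2L]),
      pearson_r = r2(r@pearsonR))
  }))
}

#' Serialise an agreement result to a JSON-ready list
#'
#' @param result a [BlandAltmanResult-class].
#' @return named list of all agreement fields.
#' @export
agreementReport <- function(result) {
  stopifnot(is(result, "BlandAltmanResult"))
  list(labels = result@labels, unit = result@unit, n = result@n,
       mean_diff = result@meanDiff, sd_diff = result@sdDiff,
       grand_mean = result@grandMean, bias_percent = result@biasPercent,
       loa_lower = result@loa[1L], loa_upper = result@loa[2L],
       ci_loa_lower = result@ciLoaLower, ci_loa_upper = result@ciLoaUpper,
       p_paired_t = result@pPairedT, pearson_r = result@pearsonR,
       prop_bias_slope = result@propBiasSlope,
       prop_bias_intercept = result@propBiasIntercept,
       p_slope = result@pSlope,
       coverage_within_loa = result@coverageWithinLoa,
       qc_flags = result@qcFlags)
}

#' Run the phantom-to-agreement pipeline end to end
#'
#' Generates a phantom cohort ([makeCohortImages()]), segments and
#' measures every retained image ([analyzeCohort()]), compares the
#' image-derived CCT/ACD/K against the generator's ground truth with
#' Bland-Altman statistics, and writes all artifacts into `outDir`:
#' the images with annotation and ground-truth CSVs, `biometry.csv`,
#' `exclusions.csv`, `agreement.json`, a comparison-table CSV
#' (`agreement_table.csv`), Bland-Altman plot PNGs, and a machine-readable
#' run manifest (`manifest.json`: configuration, seed, package version).
#'
#' @param outDir output directory.
#' @param n cohort size.
#' @param seed RNG seed recorded in the manifest and every generator call.
#' @param noise a [NoiseModel-class].
#' @param spurMissingFraction fraction of scans with unidentifiable spurs.
#' @param config a [segmentationConfig()].
#' @param width,height,fov,apexOffset raster parameters.
#' @param zone,index curvature zone (mm) and keratometric index.
#' @param plots write Bland-Altman PNGs.
#' @return invisibly, a list with `biometry`, `exclusions`, `agreement`
#'   (list of [BlandAltmanResult-class]) and `paths`.
#' @export
runPipeline <- function(outDir, n = 20, seed = 1, noise = NoiseModel(),
                        spurMissingFraction = 0,
                        config = segmentationConfig(),
                        width = 600, height = 300, fov = c(16, 6),
                        apexOffset = 1, zone = NULL, index = 1.3375,
                        plots = TRUE) {
  gen <- makeCohortImages(n, outDir, seed = seed, noise = noise,
                          spurMissingFraction = spurMissingFraction,
                          width = width, height = height, fov = fov,
                          apexOffset = apexOffset,
                          keratometricIndex = index)
  scaleX <- fov[1L] / width; scaleY <- fov[2L] / height
  res <- analyzeCohort(gen$images, gen$annotations, scaleX = scaleX,
                       scaleY = scaleY, config = config, zone = zone,
                       index = index)
  paths <- list(
    biometry = file.path(outDir, "biometry.csv"),
    exclusions = file.path(outDir, "exclusions.csv"),
    agreement = file.path(outDir, "agreement.json"),
    table = file.path(outDir, "agreement_table.csv"),
    manifest = file.path(outDir, "manifest.json"))
  utils::write.csv(res$biometry, paths$biometry, row.names = FALSE)
  utils::write.csv(res$exclusions, paths$exclusions, row.names = FALSE)

  agreement <- list()
  if (!is.null(res$biometry) && nrow(res$biometry) >= 3L) {
    mtab <- merge(res$biometry, gen$truth, by = "image_id",
                  suffixes = c("_meas", "_true"))
    mk <- function(meas, true, lab, unit) {
      ok <- is.finite(mtab[[meas]]) & is.finite(mtab[[true]])
      if (sum(ok) < 3L) return(NULL)
      blandAltman(PairedSeries(mtab[[meas]][ok], mtab[[true]][ok],
                               labels = c(lab, "ground truth"),
                               unit = unit))
    }
    agreement <- Filter(Negate(is.null), list(
      CCT = mk("cct_um_meas", "cct_um_true", "AS-OCT CCT", "um"),
      ACD = mk("acd_mm_meas", "acd_mm_true", "AS-OCT ACD", "mm"),
      K = mk("k_d", "k_ant_d", "AS-OCT K", "D")))
    utils::write.csv(agreementTable(agreement), paths$table,
                     row.names = FALSE)
    jsonlite::write_json(lapply(agreement, agreementReport),
                         paths$agreement, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    if (plots) {
      for (nm in names(agreement)) {
        r <- agreement[[nm]]
        meas <- switch(nm, CCT = "cct_um_meas", ACD = "acd_mm_meas",
                       K = "k_d")
        true <- switch(nm, CCT = "cct_um_true", ACD = "acd_mm_true",
                       K = "k_ant_d")
        ok <- is.finite(mtab[[meas]]) & is.finite(mtab[[true]])
        ser <- PairedSeries(mtab[[meas]][ok], mtab[[true]][ok],
                            labels = r@labels, unit = r@unit)
        blandAltmanPlot(ser, r,
                        file = file.path(outDir,
                                         sprintf("bland_altman_%s.png", nm)))
      }
    }
  }
  manifest <- list(
    package = "asoct",
    version = as.character(utils::packageVersion("asoct")),
    r_version = as.character(getRversion()),
    seed = seed, n = n,
    spur_missing_fraction = spurMissingFraction,
    raster = list(width = width, height = height, fov = fov,
                  apex_offset = apexOffset),
    noise = list(speckle_shape = noise@speckleShape,
                 additive_sd = noise@additiveSd,
                 salt_pepper_fraction = noise@saltPepperFraction),
    curvature_zone_mm = if (is.null(zone)) "full-chord" else zone,
    keratometric_index = index,
    segmentation = unclass(config),
    n_analysed = if (is.null(res$biometry)) 0L else nrow(res$biometry),
    n_excluded = nrow(res$exclusions))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(biometry = res$biometry, exclusions = res$exclusions,
                 agreement = agreement, paths = paths))
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment; values are parsed as numbers where possible, with
#' comma-separated values becoming vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
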