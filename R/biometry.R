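#' Locate the corneal apex on a fitted trace
#'
#' The apex is the most anterior point of the fitted anterior surface: the
#' column minimising the fitted row over the fit domain (evaluated on a
#' 0.25-px grid), ties broken toward `centerX`. A minimum sitting on the
#' domain boundary (a non-convex or monotone fit) is flagged rather than
#' rejected.
#'
#' @param trace a fitted [BoundaryTrace-class] (corneal anterior surface).
#' @param centerX tie-break/reference column, typically the image centre.
#' @return list with `apexX` (pixels) and `qc` (character, possibly empty).
#' @export
findApex <- function(trace, centerX = mean(trace@fitDomain)) {
  stopifnot(is(trace, "BoundaryTrace"))
  grid <- seq(trace@fitDomain[1L], trace@fitDomain[2L], by = 0.25)
  yv <- predictTrace(trace, grid)
  cand <- which(yv <= min(yv) + 1e-9)
  apex <- grid[cand[which.min(abs(grid[cand] - centerX))]]
  qc <- character(0L)
  if (apex <= trace@fitDomain[1L] + 0.5 || apex >= trace@fitDomain[2L] - 0.5)
    qc <- "apex at edge"
  list(apexX = apex, qc = qc)
}

#' Central corneal thickness from fitted boundaries
#'
#' Axial distance between the fitted epithelium and endothelium evaluated
#' at the apex column, converted to micrometres by the axial pixel scale.
#'
#' @param bounds a [BoundarySet-class] with epithelium and endothelium.
#' @param scaleY axial pixel size (mm per pixel).
#' @param apexX apex column; located on the epithelium fit by default.
#' @return CCT in micrometres.
#' @export
computeCct <- function(bounds, scaleY, apexX = NULL) {
  stopifnot(is(bounds, "BoundarySet"))
  tr <- bounds@traces
  if (is.null(tr$epithelium) || is.null(tr$endothelium))
    stop("epithelium and endothelium traces required")
  if (is.null(apexX)) apexX <- findApex(tr$epithelium)$apexX
  dpx <- predictTrace(tr$endothelium, apexX) - predictTrace(tr$epithelium, apexX)
  if (dpx <= 0) stop("invalid corneal thickness")
  dpx * scaleY * 1000
}

#' Aqueous depth and anterior chamber depth from fitted boundaries
#'
#' The aqueous ("internal" anterior chamber) depth is the axial distance
#' from the fitted endothelium to the fitted anterior lens surface at the
#' apex column; the reported ACD adds the corneal thickness, `acd =
#' aqueousDepth + cct/1000`, matching optical-biometer convention.
#'
#' @param bounds a [BoundarySet-class].
#' @param scaleY axial pixel size (mm per pixel).
#' @param apexX apex column; located on the epithelium fit by default.
#' @return list with `aqueousDepth` (mm), `acd` (mm) and `qc`; both depths
#'   are NA with a QC flag when the lens trace is missing.
#' @export
computeAcd <- function(bounds, scaleY, apexX = NULL) {
  stopifnot(is(bounds, "BoundarySet"))
  tr <- bounds@traces
  if (is.null(tr$endothelium))
    stop("endothelium trace required")
  if (is.null(apexX)) {
    if (is.null(tr$epithelium)) stop("epithelium trace required to find apex")
    apexX <- findApex(tr$epithelium)$apexX
  }
  if (is.null(tr$lens_anterior))
    return(list(aqueousDepth = NA_real_, acd = NA_real_,
                qc = "lens trace missing; acd not computed"))
  cct <- computeCct(bounds, scaleY, apexX = apexX)
  aq <- (predictTrace(tr$lens_anterior, apexX) -
           predictTrace(tr$endothelium, apexX)) * scaleY
  list(aqueousDepth = aq, acd = aq + cct / 1000, qc = character(0L))
}

#' Radius of curvature of a fitted boundary
#'
#' Least-squares circle fit to the fitted trace evaluated at the integer
#' columns of the fitting zone about the apex, in physical mm coordinates:
#' an algebraic (Kasa) fit solved by normal equations, then a single
#' Gauss-Newton refinement step on the geometric residuals. A radius above
#' 1e4 mm is flagged `"flat"`.
#'
#' With a 20 um axial pixel, a narrow zone gives the circle fit too little
#' sagitta to resolve the radius to clinical precision, so by default the
#' zone spans the trace's whole fit domain (the full corneal fitting
#' chord); pass a numeric `zone` to restrict it.
#'
#' @param trace a fitted [BoundaryTrace-class].
#' @param zone chord width (mm) of the fitting zone centred on the apex,
#'   or `NULL` (default) for the full fit domain of the trace.
#' @param scaleX,scaleY physical pixel sizes (mm per pixel).
#' @param apexX apex column (pixels); located on the trace by default.
#' @return list with `radius` (mm), `center` (mm, lateral/axial) and `qc`.
#' @export
fitCurvature <- function(trace, zone = NULL, scaleX, scaleY, apexX = NULL) {
  stopifnot(is(trace, "BoundaryTrace"), is.null(zone) || zone > 0)
  if (is.null(apexX)) apexX <- findApex(trace)$apexX
  if (is.null(zone)) {
    lo <- ceiling(trace@fitDomain[1L]); hi <- floor(trace@fitDomain[2L])
  } else {
    halfPx <- zone / 2 / scaleX
    lo <- ceiling(apexX - halfPx); hi <- floor(apexX + halfPx)
    if (lo < trace@fitDomain[1L] || hi > trace@fitDomain[2L])
      stop("curvature zone exceeds trace support")
  }
  cols <- lo:hi
  X <- cols * scaleX
  Y <- predictTrace(trace, cols) * scaleY
  Xc <- X - mean(X); Yc <- Y - mean(Y)
  A <- cbind(Xc, Yc, 1)
  rhs <- -(Xc^2 + Yc^2)
  beta <- tryCatch(solve(crossprod(A), crossprod(A, rhs)),
                   error = function(e) NULL)
  if (is.null(beta))
    return(list(radius = Inf, center = c(NA_real_, NA_real_), qc = "flat"))
  cx <- -beta[1L] / 2; cy <- -beta[2L] / 2
  r <- sqrt(max(cx^2 + cy^2 - beta[3L], 0))
  ## one Gauss-Newton step on geometric residuals
  di <- sqrt((Xc - cx)^2 + (Yc - cy)^2)
  if (all(di > 0) && is.finite(r) && r > 0) {
    f <- di - r
    J <- cbind(-(Xc - cx) / di, -(Yc - cy) / di, -1)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, f)),
                     error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      cx <- cx + step[1L]; cy <- cy + step[2L]; r <- r + step[3L]
    }
  }
  qc <- if (!is.finite(r) || r > 1e4) "flat" else character(0L)
  list(radius = r, center = c(cx + mean(X), cy + mean(Y)), qc = qc)
}

#' Keratometric power from a corneal radius
#'
#' Converts an anterior corneal radius of curvature to diopters with the
#' keratometric refractive index convention: `K = 1000 * (index - 1) /
#' radius`.
#'
#' @param radius corneal radius of curvature (mm); must be positive.
#' @param index keratometric refractive index (clinical standard 1.3375).
#' @return keratometry in diopters.
#' @export
#' @examples
#' keratometry(7.5)   # 45 D
keratometry <- function(radius, index = 1.3375) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive")
  1000 * (index - 1) / radius
}

#' Full biometry of one segmented B-scan
#'
#' Derives the three clinical parameters from a [BoundarySet-class]: CCT
#' (um), aqueous depth and ACD (mm), anterior and posterior corneal radii
#' (mm) from circle fits over the central zone, and the K-reading (D) from
#' the anterior radius. All measurements are evaluated on the fitted
#' curves, never on raw points.
#'
#' @param bounds a [BoundarySet-class].
#' @param scaleX,scaleY physical pixel sizes (mm per pixel).
#' @param zone curvature fitting zone (mm), `NULL` for the full corneal
#'   fitting chord; see [fitCurvature()].
#' @param index keratometric index, see [keratometry()].
#' @param imageId identifier stored in the result.
#' @return an [OcularBiometry-class].
#' @export
measureBiometry <- function(bounds, scaleX, scaleY, zone = NULL,
                            index = 1.3375, imageId = "scan") {
  stopifnot(is(bounds, "BoundarySet"))
  qc <- bounds@qcFlags
  apex <- findApex(bounds@traces$epithelium)
  qc <- c(qc, apex$qc)
  cct <- computeCct(bounds, scaleY, apexX = apex$apexX)
  acd <- computeAcd(bounds, scaleY, apexX = apex$apexX)
  qc <- c(qc, acd$qc)
  ca <- fitCurvature(bounds@traces$epithelium, zone = zone, scaleX = scaleX,
                     scaleY = scaleY, apexX = apex$apexX)
  qc <- c(qc, if (length(ca$qc)) paste("anterior", ca$qc))
  cp <- tryCatch(
    fitCurvature(bounds@traces$endothelium, zone = zone, scaleX = scaleX,
                 scaleY = scaleY, apexX = apex$apexX),
    error = function(e) list(radius = NA_real_, qc = "posterior zone unsupported"))
  qc <- c(qc, if (length(cp$qc)) paste("posterior", cp$qc))
  k <- if (is.finite(ca$radius) && ca$radius > 0 && ca$radius <= 1e4)
    keratometry(ca$radius, index) else NA_real_
  new("OcularBiometry", imageId = imageId, cct = cct,
      aqueousDepth = acd$aqueousDepth, acd = acd$acd,
      rAnterior = ca$radius, rPosterior = cp$radius, kReading = k,
      apexX = apex$apexX, qcFlags = qc)
}
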