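## Shared fixtures, built once per test run.

defaultPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- renderBScan(AnteriorSegmentGeometry(), noiseFree(),
                            imageId = "default")
    cache
  }
})

defaultSegmentation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- defaultPhantom()
      cache <<- segmentBScan(bscanImage(ph), spurs(ph))
    }
    cache
  }
})

clipToByte <- function(x) pmin(pmax(round(x), 0), 255)

## Tiny BScanImage from a plain matrix (row-major, 0-255).
miniImage <- function(m, scaleX = 1, scaleY = 1, id = "mini") {
  new("BScanImage", pixels = m, scaleX = scaleX, scaleY = scaleY,
      imageId = id)
}

## Naive reference implementation of the consecutive-run edge rule:
## literal per-column scan, used as the independent oracle.
naiveEdgeScan <- function(b, direction, top, bottom, runLength = 5L) {
  h <- nrow(b); w <- ncol(b)
  out <- rep(NA_real_, w)
  for (j in seq_len(w)) {
    for (y0 in top:bottom) {
      y1 <- y0 + 1L
      if (y1 - runLength < 1L || y1 + runLength - 1L > h) next
      above <- b[(y1 - runLength):(y1 - 1L), j]
      below <- b[y1:(y1 + runLength - 1L), j]
      hit <- if (direction == "open_to_tissue")
        all(above == 0) && all(below == 1)
      else all(above == 1) && all(below == 0)
      if (hit) { out[j] <- y0; break }
    }
  }
  out
}

## First-principles Bland-Altman recomputation: explicit sums only
## (distribution functions allowed, no model/summary calls).
bruteForceBlandAltman <- function(a, b) {
  n <- length(a)
  d <- a - b; m <- (a + b) / 2
  md <- sum(d) / n
  s <- sqrt(sum((d - md)^2) / (n - 1))
  gm <- sum(m) / n
  loa <- c(md - 1.96 * s, md + 1.96 * s)
  half <- 1.96 * s * sqrt(3 / n)
  tstat <- md / (s / sqrt(n))
  am <- sum(a) / n; bm <- sum(b) / n
  r <- sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
  mm <- sum(m) / n
  sxx <- sum((m - mm)^2)
  slope <- sum((m - mm) * (d - md)) / sxx
  inter <- md - slope * mm
  resid <- d - inter - slope * m
  seSlope <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(n = n, meanDiff = md, sdDiff = s, grandMean = gm,
       biasPercent = 100 * md / gm, loa = loa,
       ciLoaLower = c(loa[1] - half, loa[1] + half),
       ciLoaUpper = c(loa[2] - half, loa[2] + half),
       pPairedT = 2 * stats::pt(-abs(tstat), n - 1),
       pearsonR = r, propBiasSlope = slope, propBiasIntercept = inter,
       pSlope = 2 * stats::pt(-abs(slope / seSlope), n - 2),
       coverage = 100 * mean(d >= loa[1] & d <= loa[2]))
}

## Phantom recovery errors for a set of geometries (shared by unit and
## acceptance tests).
recoveryErrors <- function(geoms, noise, seedBase = 0L,
                           config = segmentationConfig()) {
  out <- NULL
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    ph <- renderBScan(g, noise, seed = seedBase + i,
                      imageId = sprintf("ph%03d", i))
    img <- bscanImage(ph)
    bio <- measureBiometry(segmentBScan(img, spurs(ph), config),
                           img@scaleX, img@scaleY)
    out <- rbind(out, data.frame(
      cct = bio@cct - g@cct,
      acd = bio@acd - (g@aqueousDepth + g@cct / 1000),
      k = bio@kReading - keratometry(g@anteriorRadius)))
  }
  out
}
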