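## Build a BoundarySet directly from analytic traces.
mkTrace <- function(coefs, center, domain, label) {
  new("BoundaryTrace", x = seq(domain[1L], domain[2L]),
      yRaw = rep(NA_real_, domain[2L] - domain[1L] + 1L),
      coefficients = coefs, fitCenter = center, fitDomain = domain,
      label = label)
}
mkBounds <- function(traces) {
  new("BoundarySet", traces = traces,
      spurs = SpurPair(c(10, 50), c(90, 50), "fixture"),
      qcFlags = character(0L))
}

test_that("apex location respects symmetry, shifts and degeneracy", {
  ph <- defaultPhantom()
  bs <- defaultSegmentation()
  apex <- findApex(traces(bs)$epithelium)
  expect_lt(abs(apex$apexX - 299.5), 1)
  expect_length(apex$qc, 0L)
  ## laterally shifted parabola: apex follows the shift
  tr <- mkTrace(c(80, 0, 0.001), center = 150, domain = c(0, 300),
                label = "epithelium")  # vertex at fitCenter = 150
  trShift <- mkTrace(c(80, -2 * 0.001 * 30, 0.001), center = 150,
                     domain = c(0, 300), label = "epithelium")
  expect_equal(findApex(tr)$apexX, 150)
  expect_equal(findApex(trShift)$apexX, 180, tolerance = 0.26)
  ## monotone trace: apex pinned to the domain edge, flagged
  mono <- mkTrace(c(50, 0.1), center = 0, domain = c(0, 100),
                  label = "epithelium")
  expect_identical(findApex(mono)$qc, "apex at edge")
})

test_that("a laterally shifted phantom shifts the measured apex equally", {
  g <- AnteriorSegmentGeometry()
  ph2 <- renderBScan(g, noiseFree(), lateralShift = 0.8)  # 0.8 mm = 30 px
  a1 <- findApex(traces(defaultSegmentation())$epithelium)$apexX
  bs2 <- segmentBScan(bscanImage(ph2), spurs(ph2))
  a2 <- findApex(traces(bs2)$epithelium)$apexX
  expect_equal(a2 - a1, 30, tolerance = 1)
})

test_that("CCT recovers the generating thickness within one axial pixel", {
  bs <- defaultSegmentation()
  expect_equal(computeCct(bs, scaleY = 0.02), 560, tolerance = 20)
  g <- AnteriorSegmentGeometry(cct = 600)
  ph <- renderBScan(g, noiseFree())
  bs2 <- segmentBScan(bscanImage(ph), spurs(ph))
  expect_equal(computeCct(bs2, scaleY = 0.02), 600, tolerance = 20)
})

test_that("crossing or identical corneal traces are invalid", {
  epi <- mkTrace(c(60, 0, 0.002), 150, c(0, 300), "epithelium")
  endo <- mkTrace(c(60, 0, 0.002), 150, c(0, 300), "endothelium")
  bounds <- mkBounds(list(epithelium = epi, endothelium = endo))
  expect_error(computeCct(bounds, scaleY = 0.02),
               "invalid corneal thickness")
  expect_error(computeCct(mkBounds(list(epithelium = epi)), 0.02),
               "required")
})

test_that("ACD is the aqueous depth plus corneal thickness", {
  bs <- defaultSegmentation()
  acd <- computeAcd(bs, scaleY = 0.02)
  expect_equal(acd$acd, 3.29, tolerance = 0.02)
  expect_equal(acd$aqueousDepth, 2.73, tolerance = 0.02)
  expect_equal(acd$acd, acd$aqueousDepth + computeCct(bs, 0.02) / 1000,
               tolerance = 1e-12)
  ## lens touching the cornea: acd collapses to cct/1000
  epi <- mkTrace(c(50, 0, 0.002), 150, c(0, 300), "epithelium")
  endo <- mkTrace(c(78, 0, 0.002), 150, c(0, 300), "endothelium")
  lens <- mkTrace(c(78, 0, 0.002), 150, c(0, 300), "lens_anterior")
  b0 <- mkBounds(list(epithelium = epi, endothelium = endo,
                      lens_anterior = lens))
  r <- computeAcd(b0, scaleY = 0.02)
  expect_equal(r$aqueousDepth, 0)
  expect_equal(r$acd, computeCct(b0, 0.02) / 1000)
  ## missing lens: QC flag, no ACD
  b1 <- mkBounds(list(epithelium = epi, endothelium = endo))
  r1 <- computeAcd(b1, scaleY = 0.02)
  expect_true(is.na(r1$acd))
  expect_match(r1$qc, "lens trace missing")
})

test_that("circle fitting recovers an exact circle and flags flat traces", {
  sx <- 16 / 600; sy <- 6 / 300
  x <- 230:370
  R <- 7.5
  y <- (1 + R - sqrt(R^2 - ((x - 300) * sx)^2)) / sy
  tr <- smoothAndFit(x, y, degree = 4, smoothingWindow = 1,
                     label = "epithelium")
  r <- fitCurvature(tr, zone = 3, scaleX = sx, scaleY = sy)
  expect_equal(r$radius, 7.5, tolerance = 1e-3)
  ## full-domain default zone
  r2 <- fitCurvature(tr, scaleX = sx, scaleY = sy)
  expect_equal(r2$radius, 7.5, tolerance = 1e-3)
  ## straight line: flagged flat
  flat <- mkTrace(c(100, 1e-7), 300, c(100, 500), "epithelium")
  rf <- fitCurvature(flat, scaleX = sx, scaleY = sy, apexX = 300)
  expect_true(rf$radius > 1e4 || "flat" %in% rf$qc)
  ## zone wider than the trace support
  expect_error(fitCurvature(tr, zone = 30, scaleX = sx, scaleY = sy),
               "zone exceeds")
})

test_that("keratometry follows the keratometric-index convention", {
  expect_equal(keratometry(7.5), 45)
  expect_equal(keratometry(6.75), 50)
  expect_equal(keratometry(7.2), 46.875)
  radii <- seq(5, 10, by = 0.25)
  expect_true(all(diff(keratometry(radii)) < 0))
  expect_error(keratometry(0), "positive")
  expect_error(keratometry(-3), "positive")
})

test_that("biometry is invariant to a joint rescaling of pixels and geometry", {
  ## same physical eye rendered at twice the pixel density
  g <- AnteriorSegmentGeometry()
  ph1 <- renderBScan(g, noiseFree(), width = 600, height = 300)
  ph2 <- renderBScan(g, noiseFree(), width = 1200, height = 600)
  b1 <- measureBiometry(segmentBScan(bscanImage(ph1), spurs(ph1)),
                        16 / 600, 6 / 300)
  b2 <- measureBiometry(segmentBScan(bscanImage(ph2), spurs(ph2)),
                        16 / 1200, 6 / 600)
  expect_equal(b1@cct, b2@cct, tolerance = 10)
  expect_equal(b1@acd, b2@acd, tolerance = 0.01)
  expect_equal(b1@kReading, b2@kReading, tolerance = 0.1)
})

test_that("acd identity holds exactly for every processed image", {
  res <- recoveryErrors(sampleGeometries(3, seed = 55), noiseFree())
  expect_equal(nrow(res), 3L)
  ph <- defaultPhantom()
  bio <- measureBiometry(defaultSegmentation(), 16 / 600, 6 / 300)
  expect_equal(bio@acd - bio@aqueousDepth - bio@cct / 1000, 0,
               tolerance = 1e-12)
})
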