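test_that("geometry and noise constructors enforce their invariants", {
  g <- AnteriorSegmentGeometry()
  expect_s4_class(g, "AnteriorSegmentGeometry")
  expect_lt(g@spurLeft[1L], g@spurRight[1L])
  expect_error(AnteriorSegmentGeometry(cct = -5), "positive")
  expect_error(AnteriorSegmentGeometry(irisDepth = 5, aqueousDepth = 2.7),
               "aqueousDepth")
  expect_error(AnteriorSegmentGeometry(tissueIntensity = 10,
                                       backgroundIntensity = 20),
               "exceed")
  expect_error(NoiseModel(saltPepperFraction = 1), "saltPepper")
  expect_error(PairedCohortSpec(1, 0, 1), "n must be")
})

test_that("noise-free rendering matches the analytic model at the apex", {
  ph <- defaultPhantom()
  img <- bscanImage(ph)
  expect_equal(dim(pixelMatrix(img)), c(300L, 600L))
  expect_equal(unname(pixelScale(img)), c(16 / 600, 6 / 300))
  ## apex corneal thickness: 560 um at 20 um/px = 28 axial pixels of tissue
  gt <- groundTruth(ph)
  i <- which(gt$x == 300L)
  expect_equal(gt$yPosterior[i] - gt$yAnterior[i], 28, tolerance = 1e-3)
  col <- pixelMatrix(img)[, 301L]
  runs <- rle(col > 100)
  expect_equal(runs$lengths[runs$values][1L], 28L)
})

test_that("rendered surface crossings track the analytic curves within 0.5 px", {
  ph <- defaultPhantom()
  p <- pixelMatrix(bscanImage(ph))
  gt <- groundTruth(ph)
  ok <- !is.na(gt$yAnterior) & gt$yAnterior > 1
  firstTissue <- apply(p[, gt$x[ok] + 1L, drop = FALSE] > 100, 2L,
                       function(col) which(col)[1L] - 1L)
  ## half-open region convention: first tissue row is ceiling(yAnterior),
  ## so the rasterised crossing sits within 1 px above the analytic curve
  d <- firstTissue - gt$yAnterior[ok]
  expect_true(all(d >= -1e-9 & d < 1))
  expect_true(all(abs(firstTissue - 0.5 - gt$yAnterior[ok]) <= 0.5 + 1e-9))
})

test_that("ground-truth curves have a single axial crossing per column", {
  ph <- defaultPhantom()
  p <- pixelMatrix(bscanImage(ph))
  gt <- groundTruth(ph)
  corneal <- !is.na(gt$yAnterior) & !is.na(gt$yPosterior)
  for (x in gt$x[corneal][seq(1, sum(corneal), by = 25)]) {
    col <- p[, x + 1L] > 100
    band <- col[seq_len(floor(gt$yPosterior[gt$x == x]) + 1L)]
    expect_lte(sum(abs(diff(band))), 2L)  # one rise and at most one fall
  }
})

test_that("rendering is deterministic and noise-free output is seed-independent", {
  g <- AnteriorSegmentGeometry()
  n1 <- renderBScan(g, NoiseModel(), seed = 42)
  n2 <- renderBScan(g, NoiseModel(), seed = 42)
  n3 <- renderBScan(g, NoiseModel(), seed = 43)
  expect_identical(pixelMatrix(bscanImage(n1)), pixelMatrix(bscanImage(n2)))
  expect_false(identical(pixelMatrix(bscanImage(n1)),
                         pixelMatrix(bscanImage(n3))))
  f1 <- renderBScan(g, noiseFree(), seed = 1)
  f2 <- renderBScan(g, noiseFree(), seed = 99)
  expect_identical(pixelMatrix(bscanImage(f1)), pixelMatrix(bscanImage(f2)))
})

test_that("geometry outside the field of view names the offending surface", {
  g <- AnteriorSegmentGeometry(aqueousDepth = 6)
  expect_error(renderBScan(g, noiseFree()), "lens")
  expect_error(renderBScan(AnteriorSegmentGeometry(), noiseFree(),
                           fov = c(10, 6)), "spur")
  expect_error(renderBScan(AnteriorSegmentGeometry(), noiseFree(),
                           apexOffset = -1), "cornea")
  expect_error(renderBScan(AnteriorSegmentGeometry(), noiseFree(),
                           width = 20), "width")
})

test_that("simulateCohort follows its generating model", {
  ## no bias, no noise: the two modalities are identical
  co <- simulateCohort(PairedCohortSpec(50, 10, 2, 0, 0, 0, seed = 3))
  expect_identical(co$modalityA, co$modalityB)
  expect_identical(co$modalityA, co$truth)
  ## deterministic given seed
  s <- PairedCohortSpec(100, 3.13, 0.35, 0.16, 0, 0.14, seed = 11)
  expect_identical(simulateCohort(s), simulateCohort(s))
  ## constant bias shows up as the mean difference
  co <- simulateCohort(PairedCohortSpec(5000, 3.13, 0.35, 0.16, 0, 0.14,
                                        seed = 5))
  d <- co$modalityB - co$modalityA
  expect_equal(mean(d), 0.16, tolerance = 4 * sd(d) / sqrt(5000))
})

test_that("difference mean stays within 4 SE of its target over many cohorts", {
  nrep <- 500L; n <- 60L
  means <- withr::with_seed(21, {
    vapply(seq_len(nrep), function(i) {
      co <- simulateCohort(PairedCohortSpec(n, 5, 1, 0.3, 0.1, 0.2,
                                            seed = 5000 + i))
      mean(co$modalityB - co$modalityA)
    }, numeric(1L))
  })
  target <- 0.3 + 0.1 * 5
  se <- sd(means) / sqrt(nrep)
  expect_lt(abs(mean(means) - target), 4 * se)
})

test_that("difference-on-average slope matches the analytic attenuation", {
  ## d = b1*t + (eB - eA), m = (1 + b1/2)*t + (eA + eB)/2 =>
  ## slope = b1*(1 + b1/2)*Vt / ((1 + b1/2)^2*Vt + Ve/2)
  b1 <- 0.1; vt <- 1; ve <- 0.2^2
  theory <- b1 * (1 + b1 / 2) * vt / ((1 + b1 / 2)^2 * vt + ve / 2)
  co <- simulateCohort(PairedCohortSpec(200000, 5, sqrt(vt), 0, b1,
                                        sqrt(ve), seed = 8))
  d <- co$modalityB - co$modalityA
  m <- (co$modalityA + co$modalityB) / 2
  slope <- stats::cov(d, m) / stats::var(m)
  expect_equal(slope, theory, tolerance = 0.02)
  ## noise-free limit from the same algebra: b1 / (1 + b1/2)
  expect_equal(b1 * (1 + b1 / 2) / (1 + b1 / 2)^2, 0.1 / 1.05)
})

test_that("calibrateCohortSpec reproduces the stated modality moments", {
  spec <- kReadingCohortSpec(n = 200000, seed = 13)
  co <- simulateCohort(spec)
  expect_equal(mean(co$modalityA), 43.98, tolerance = 0.02)
  expect_equal(mean(co$modalityB), 46.79, tolerance = 0.02)
  expect_equal(sd(co$modalityA), 1.53, tolerance = 0.02)
  expect_equal(sd(co$modalityB), 2.72, tolerance = 0.02)
  expect_equal(cor(co$modalityA, co$modalityB), 0.50, tolerance = 0.01)
  expect_equal(sd(co$modalityB - co$modalityA), 2.36, tolerance = 0.02)
})

test_that("makeCohortImages writes images, annotations and ground truth", {
  d <- withr::local_tempdir()
  res <- makeCohortImages(5, d, seed = 4, noise = noiseFree())
  expect_length(res$images, 5L)
  expect_true(all(file.exists(res$images)))
  expect_equal(nrow(res$annotations), 5L)
  expect_equal(nrow(res$truth), 5L)
  expect_named(res$annotations,
               c("image_id", "spur_left_x", "spur_left_y", "spur_right_x",
                 "spur_right_y", "spur_visible"))
  expect_named(res$truth,
               c("image_id", "cct_um", "aqueous_mm", "acd_mm", "r_ant_mm",
                 "r_post_mm", "k_ant_d"))
  expect_true(all(res$annotations$spur_visible == 1L))
  ## file contents reproducible under the same seed
  d2 <- withr::local_tempdir()
  res2 <- makeCohortImages(5, d2, seed = 4, noise = noiseFree())
  expect_identical(unname(tools::md5sum(res$images)),
                   unname(tools::md5sum(res2$images)))
})

test_that("spur-missing flags appear at the configured rate", {
  d <- withr::local_tempdir()
  frac <- 49 / 1118
  res <- makeCohortImages(250, d, seed = 6, noise = noiseFree(),
                          spurMissingFraction = frac)
  nMissing <- sum(res$annotations$spur_visible == 0L)
  expect_true(anyNA(res$annotations$spur_left_x[res$annotations$spur_visible == 0L]))
  ## binomial 4-sigma band around 250 * 49/1118 ~ 11
  expect_lt(abs(nMissing - 250 * frac), 4 * sqrt(250 * frac * (1 - frac)) + 1)
})
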