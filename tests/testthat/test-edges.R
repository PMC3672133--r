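mkBinary <- function(m) new("BinaryImage", pixels = m, thresholdUsed = 128)

test_that("the 5/5 run rule fires exactly where its definition says", {
  col <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1)
  r <- detectEdgePoints(mkBinary(col), "open_to_tissue", c(0, 9))
  expect_equal(r$y, 5)
  ## only 4 zeros above: no qualifying row
  col2 <- matrix(c(rep(0, 4), rep(1, 6)), ncol = 1)
  r2 <- detectEdgePoints(mkBinary(col2), "open_to_tissue", c(0, 9))
  expect_true(is.na(r2$y))
  ## inverted polarity
  r3 <- detectEdgePoints(mkBinary(1 - col), "tissue_to_open", c(0, 9))
  expect_equal(r3$y, 5)
  ## first (topmost) qualifying row wins
  col4 <- matrix(c(rep(0, 5), rep(1, 6), rep(0, 5), rep(1, 6)), ncol = 1)
  r4 <- detectEdgePoints(mkBinary(col4), "open_to_tissue", c(0, 21))
  expect_equal(r4$y, 5)
})

test_that("a short search band is an error", {
  b <- mkBinary(matrix(0, 30, 4))
  expect_error(detectEdgePoints(b, "open_to_tissue", c(3, 11)),
               "shorter than 10 px")
  expect_error(detectEdgePoints(b, "open_to_tissue", c(-2, 40)), NA)
})

test_that("the edge rule is translation-equivariant", {
  base <- c(rep(0, 8), rep(1, 12), rep(0, 20))
  for (k in c(0L, 3L, 7L, 11L)) {
    col <- matrix(c(rep(0, k), base, rep(0, 12 - k)), ncol = 1)
    r <- detectEdgePoints(mkBinary(col), "open_to_tissue",
                          c(0, nrow(col) - 1L))
    expect_equal(r$y, 8 + k)
  }
})

test_that("vectorised detection equals a naive per-column scan on random images", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      m <- matrix(rbinom(40 * 25, 1, runif(1, 0.2, 0.8)), nrow = 40)
      b <- mkBinary(m)
      for (dir in c("open_to_tissue", "tissue_to_open")) {
        top <- sample(0:10, 1); bottom <- sample(25:39, 1)
        got <- detectEdgePoints(b, dir, c(top, bottom))
        want <- naiveEdgeScan(m, dir, top, bottom)
        expect_identical(got$y, want)
      }
    }
  })
})

test_that("per-column bands and column subsets are honoured", {
  ph <- defaultPhantom()
  b <- binarize(bscanImage(ph), 100)
  cols <- c(250L, 300L, 350L)
  gt <- groundTruth(ph)
  truth <- gt$yAnterior[match(cols, gt$x)]
  band <- rbind(truth - 20, truth + 20)
  r <- detectEdgePoints(b, "open_to_tissue", band = band, columns = cols)
  expect_equal(r$x, cols)
  expect_true(all(abs(r$y - truth) < 1))
  ## a band strictly below the surface misses it
  r2 <- detectEdgePoints(b, "open_to_tissue",
                         band = rbind(truth + 5, truth + 30), columns = cols)
  expect_true(all(is.na(r2$y) | r2$y > truth + 4))
})

test_that("noise-free anterior detection stays within 1 px of ground truth", {
  ph <- defaultPhantom()
  b <- binarize(bscanImage(ph), computeThreshold(bscanImage(ph)))
  gt <- groundTruth(ph)
  corneal <- gt$x[!is.na(gt$yPosterior)]
  r <- detectEdgePoints(b, "open_to_tissue", c(0, 299), columns = corneal)
  err <- r$y - gt$yAnterior[match(corneal, gt$x)]
  expect_gte(mean(abs(err) <= 1, na.rm = TRUE), 0.99)
  expect_gte(mean(!is.na(err)), 0.99)
})
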