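test_that("limits of agreement follow mean difference +/- 1.96 SD", {
  expect_equal(limitsOfAgreement(16.75, 17.35), c(-17.256, 50.756))
  expect_equal(roundHalfAway(limitsOfAgreement(16.75, 17.35), 2),
               c(-17.26, 50.76))
  s <- 2.34
  expect_equal(limitsOfAgreement(0, s), c(-1.96 * s, 1.96 * s))
  loa <- limitsOfAgreement(0.16, 0.20)
  expect_equal(roundHalfAway(loa[2], 2), 0.55)
  ## lower limit from the rounded inputs is -0.232 -> prints -0.23
  expect_equal(roundHalfAway(loa[1], 2), -0.23)
  expect_error(limitsOfAgreement(1, -0.1), ">= 0")
})

test_that("LOA algebra holds for arbitrary inputs", {
  withr::with_seed(31, {
    for (i in 1:25) {
      md <- rnorm(1, 0, 10); s <- rexp(1, 1 / 5)
      loa <- limitsOfAgreement(md, s)
      expect_equal(diff(loa), 2 * 1.96 * s)
      expect_equal(mean(loa), md)
    }
  })
})

test_that("LOA confidence intervals use SE = sd * sqrt(3/n)", {
  ci <- loaConfidenceIntervals(16.75, 17.35, 1069)
  half <- 1.96 * 17.35 * sqrt(3 / 1069)
  expect_equal(roundHalfAway(half, 2), 1.80)
  ## the intervals are centred on the limits with that half-width; the
  ## printed table applies the (rounded) half-width to the rounded limits
  expect_equal(mean(ci$lower), limitsOfAgreement(16.75, 17.35)[1L])
  expect_equal(mean(ci$upper), limitsOfAgreement(16.75, 17.35)[2L])
  loaPrinted <- roundHalfAway(limitsOfAgreement(16.75, 17.35), 2)
  expect_equal(loaPrinted[1L] + c(-1.80, 1.80), c(-19.06, -15.46))
  expect_equal(loaPrinted[2L] + c(-1.80, 1.80), c(48.96, 52.56))
  expect_lt(max(abs(unlist(ci) -
                    c(loaPrinted[1L] + c(-1.80, 1.80),
                      loaPrinted[2L] + c(-1.80, 1.80)))), 0.01)
  ## zero SD collapses the intervals; large n shrinks them monotonically
  z <- loaConfidenceIntervals(1, 0, 100)
  expect_equal(diff(z$lower), 0)
  w <- vapply(c(10, 100, 1000, 1e5), function(n)
    diff(loaConfidenceIntervals(0, 1, n)$lower), numeric(1L))
  expect_true(all(diff(w) < 0))
  expect_error(loaConfidenceIntervals(0, 1, 2), "n must be")
})

test_that("percentage bias divides the mean difference by the grand mean", {
  expect_equal(roundHalfAway(biasPercent(16.75, 552.37), 2), 3.03)
  expect_equal(roundHalfAway(biasPercent(2.81, 45.39), 2), 6.19)
  expect_equal(biasPercent(0, 123), 0)
  expect_error(biasPercent(1, 0), "zero")
})

test_that("bland-altman trivial identities hold", {
  withr::with_seed(5, a <- rnorm(40, 10, 2))
  r <- blandAltman(PairedSeries(a, a, c("x", "y"), "mm"))
  expect_equal(r@meanDiff, 0)
  expect_equal(r@sdDiff, 0)
  expect_equal(r@loa, c(0, 0))
  expect_equal(r@coverageWithinLoa, 100)
  ## swapped order: differences mirror, correlation and grand mean invariant
  withr::with_seed(6, b <- a + rnorm(40, 0.5, 0.3))
  r1 <- blandAltman(PairedSeries(a, b, c("a", "b"), "mm"))
  r2 <- blandAltman(PairedSeries(b, a, c("b", "a"), "mm"))
  expect_equal(r1@meanDiff, -r2@meanDiff)
  expect_equal(r1@loa, -rev(r2@loa))
  expect_equal(r1@pearsonR, r2@pearsonR)
  expect_equal(r1@grandMean, r2@grandMean)
  ## constant identical series: flagged, not an exception
  rc <- blandAltman(PairedSeries(rep(3, 10), rep(3, 10), c("a", "b"), ""))
  expect_true(is.na(rc@pearsonR))
  expect_gt(length(rc@qcFlags), 0L)
})

test_that("bland-altman equals the first-principles recomputation", {
  withr::with_seed(41, {
    for (i in 1:30) {
      n <- sample(5:50, 1)
      a <- rnorm(n, 50, 10)
      b <- a + rnorm(n, 1, 2)
      got <- blandAltman(PairedSeries(a, b, c("a", "b"), "u"))
      want <- bruteForceBlandAltman(a, b)
      for (f in c("meanDiff", "sdDiff", "grandMean", "biasPercent",
                  "pPairedT", "pearsonR", "propBiasSlope",
                  "propBiasIntercept", "pSlope"))
        expect_equal(slot(got, f), want[[f]], tolerance = 1e-10)
      expect_equal(got@loa, want$loa, tolerance = 1e-10)
      expect_equal(got@ciLoaLower, want$ciLoaLower, tolerance = 1e-10)
      expect_equal(got@ciLoaUpper, want$ciLoaUpper, tolerance = 1e-10)
      expect_equal(got@coverageWithinLoa, want$coverage, tolerance = 1e-10)
    }
  })
})

test_that("proportional-bias band behaves on exact and noisy data", {
  ## exact line: zero-width band, every point inside, slope recovered
  m <- seq(40, 50, length.out = 30)
  d <- 0.5 * m - 19
  a <- m + d / 2; b <- m - d / 2
  pb <- proportionalBiasBand(PairedSeries(a, b, c("a", "b"), "D"))
  expect_equal(pb$slope, 0.5, tolerance = 1e-8)
  expect_equal(pb$fractionInside, 1)
  expect_lt(max(pb$band$upr - pb$band$lwr), 1e-6)
  ## degenerate x-variance
  expect_error(proportionalBiasBand(PairedSeries(rep(1, 12), rep(1, 12),
                                                 c("a", "b"), "")),
               "degenerate")
  expect_error(proportionalBiasBand(PairedSeries(1:5, 2:6, c("a", "b"), "")),
               "at least 10")
})

test_that("slope-0 cohorts keep ~95% of points inside the prediction band", {
  fr <- withr::with_seed(51, {
    vapply(1:40, function(i) {
      co <- simulateCohort(acdCohortSpec(n = 300, seed = 7000 + i))
      proportionalBiasBand(PairedSeries(co$modalityB, co$modalityA,
                                        c("oct", "ref"), "mm"))$fractionInside
    }, numeric(1L))
  })
  expect_equal(mean(fr), 0.95, tolerance = 0.01)
})

test_that("the omnibus normality test matches its reference values", {
  ## reference statistics computed independently with scipy.stats
  r1 <- dagostinoPearsonTest(c(2, 7, 4, 9, 1, 5, 8, 3, 6, 10, 12, 2, 5, 7,
                               9, 4))
  expect_equal(r1$statistic, 0.6962052280835909, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.7060264242721457, tolerance = 1e-10)
  expect_equal(r1$z.skewness, 0.4558464150783674, tolerance = 1e-10)
  expect_equal(r1$z.kurtosis, -0.6988628434419673, tolerance = 1e-10)
  r2 <- dagostinoPearsonTest(c(1, 1, 2, 2, 3, 3, 4, 5, 8, 13, 21, 34))
  expect_equal(r2$statistic, 12.468585239640923, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.001961015907593501, tolerance = 1e-10)
  expect_error(dagostinoPearsonTest(1:5), "at least 8")
})

test_that("assumption checks pass on normal differences and fail on skewed ones", {
  res <- withr::with_seed(61, {
    list(
      normPass = mean(vapply(1:60, function(i) {
        d <- rnorm(300)
        a <- rnorm(300, 50, 2); b <- a - d
        assumptionChecks(PairedSeries(a, b, c("a", "b"), ""))$normality$pass
      }, logical(1L))),
      skewFail = mean(vapply(1:60, function(i) {
        d <- rexp(300)
        a <- rnorm(300, 50, 2); b <- a - d
        !assumptionChecks(PairedSeries(a, b, c("a", "b"), ""))$normality$pass
      }, logical(1L))))
  })
  expect_gte(res$normPass, 0.9)
  expect_gte(res$skewFail, 0.99)
  degen <- assumptionChecks(PairedSeries(1:20, 1:20, c("a", "b"), ""))
  expect_true(degen$degenerate)
})

test_that("group summaries report per-group mean and SD", {
  tab <- data.frame(group = c("a", "a", "a", "b", "b", "c"),
                    acd = c(3.1, 3.3, 3.2, 2.9, 3.0, 3.4))
  gs <- groupSummaries(tab, "group", "acd")
  expect_equal(gs$n, c(3L, 2L, 1L))
  expect_equal(gs$acd_mean[1], mean(c(3.1, 3.3, 3.2)))
  expect_true(is.na(gs$acd_sd[gs$group == "c"]))
  ## single group equals the global summary
  g1 <- groupSummaries(tab[1:3, ], "group", "acd")
  expect_equal(g1$acd_mean, mean(tab$acd[1:3]))
  expect_warning(groupSummaries(
    data.frame(group = factor("a", levels = c("a", "b")), v = 1),
    "group"), "empty")
})

test_that("exclusion accounting reports the retained percentage", {
  ex <- exclusionSummary(1118, 49)
  expect_equal(ex$nRetained, 1069L)
  expect_equal(round(ex$percentRetained), 96)
  expect_error(exclusionSummary(10, 11), "nExcluded")
})
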