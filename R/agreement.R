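#' Construct a paired-measurement series
#'
#' @param valuesA,valuesB aligned measurements of the same eyes; A is the
#'   device under evaluation, B the reference instrument. Differences are
#'   always A - B.
#' @param labels names of the two modalities.
#' @param unit measurement unit.
#' @return a [PairedSeries-class].
#' @export
PairedSeries <- function(valuesA, valuesB, labels = c("A", "B"),
                         unit = "") {
  new("PairedSeries", valuesA = as.numeric(valuesA),
      valuesB = as.numeric(valuesB), labels = labels, unit = unit)
}

#' 95% limits of agreement
#'
#' `meanDiff +/- 1.96 * sdDiff`.
#'
#' @param meanDiff mean of the paired differences.
#' @param sdDiff SD of the paired differences (>= 0).
#' @return `c(lower, upper)`.
#' @export
#' @examples
#' limitsOfAgreement(16.75, 17.35)
limitsOfAgreement <- function(meanDiff, sdDiff) {
  if (sdDiff < 0) stop("sdDiff must be >= 0")
  c(meanDiff - 1.96 * sdDiff, meanDiff + 1.96 * sdDiff)
}

#' Confidence intervals of the limits of agreement
#'
#' Each limit carries the classic large-sample standard error
#' `sdDiff * sqrt(3/n)`; the 95% interval is the limit `+/- 1.96 * SE`.
#'
#' @param meanDiff,sdDiff mean and SD of the paired differences.
#' @param n number of pairs (>= 3).
#' @return list with `lower` and `upper`, each a `c(lo, hi)` interval.
#' @export
loaConfidenceIntervals <- function(meanDiff, sdDiff, n) {
  if (n < 3) stop("n must be >= 3")
  loa <- limitsOfAgreement(meanDiff, sdDiff)
  half <- 1.96 * sdDiff * sqrt(3 / n)
  list(lower = c(loa[1L] - half, loa[1L] + half),
       upper = c(loa[2L] - half, loa[2L] + half))
}

#' Percentage bias
#'
#' The mean difference expressed as a percentage of the grand mean of the
#' measured parameter.
#'
#' @param meanDiff mean of the paired differences.
#' @param grandMean mean of the per-pair averages; must be nonzero.
#' @return bias in percent.
#' @export
#' @examples
#' biasPercent(16.75, 552.37)
biasPercent <- function(meanDiff, grandMean) {
  if (grandMean == 0) stop("grand mean is zero")
  100 * meanDiff / grandMean
}

#' Bland-Altman agreement analysis of a paired series
#'
#' Computes differences `a - b` and averages `(a + b)/2` and fills every
#' agreement quantity: mean and SD of the differences, grand mean,
#' percentage bias, 95% limits of agreement with their confidence
#' intervals, two-sided paired t-test, Pearson correlation between the two
#' modality vectors, ordinary least squares of difference on average with
#' a two-sided slope test (the proportional-bias check), and the
#' percentage of differences inside the limits. Degenerate inputs
#' (constant identical series) yield NA statistics with QC flags, not
#' errors.
#'
#' @param series a [PairedSeries-class].
#' @return a [BlandAltmanResult-class].
#' @export
#' @examples
#' co <- simulateCohort(acdCohortSpec(seed = 42))
#' blandAltman(PairedSeries(co$modalityB, co$modalityA,
#'                          c("AS-OCT", "IOLMaster"), "mm"))
blandAltman <- function(series) {
  stopifnot(is(series, "PairedSeries"))
  validObject(series)
  a <- series@valuesA; b <- series@valuesB
  n <- length(a)
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d); s <- stats::sd(d)
  gm <- mean(m)
  qc <- character(0L)
  loa <- limitsOfAgreement(md, s)
  ci <- loaConfidenceIntervals(md, s, n)
  bias <- if (gm != 0) biasPercent(md, gm) else {
    qc <- c(qc, "zero grand mean; bias percent undefined"); NA_real_
  }
  pT <- if (s > 0) stats::t.test(a, b, paired = TRUE)$p.value else {
    qc <- c(qc, "constant differences; paired t-test undefined"); NA_real_
  }
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else {
    qc <- c(qc, "constant series; correlation undefined"); NA_real_
  }
  if (stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)$coefficients
    slope <- sm[2L, 1L]; inter <- sm[1L, 1L]
    pS <- if (nrow(sm) >= 2L && is.finite(sm[2L, 4L])) sm[2L, 4L] else NA_real_
  } else {
    qc <- c(qc, "constant averages; proportional-bias fit undefined")
    slope <- NA_real_; inter <- NA_real_; pS <- NA_real_
  }
  cov <- 100 * mean(d >= loa[1L] - 1e-12 & d <= loa[2L] + 1e-12)
  new("BlandAltmanResult", n = n, meanDiff = md, sdDiff = s, grandMean = gm,
      biasPercent = bias, loa = loa, ciLoaLower = ci$lower,
      ciLoaUpper = ci$upper, pPairedT = pT, pearsonR = r,
      propBiasSlope = slope, propBiasIntercept = inter, pSlope = pS,
      coverageWithinLoa = cov, labels = series@labels, unit = series@unit,
      qcFlags = qc)
}

#' Difference-on-average regression with a 95% prediction band
#'
#' Regresses the paired differences on the per-pair averages, reports the
#' slope with its two-sided test, and evaluates the standard regression
#' prediction interval on a grid spanning the observed averages — the
#' proportional-bias analysis drawn on a Bland-Altman plot.
#'
#' @param series a [PairedSeries-class] with n >= 10.
#' @param level prediction level (default 0.95).
#' @param gridLength grid points across the observed average range.
#' @return list with `slope`, `intercept`, `pSlope`, `band` (data.frame
#'   `average`, `fit`, `lwr`, `upr`), `fractionInside` (fraction of
#'   observed points inside the band) and `level`.
#' @export
proportionalBiasBand <- function(series, level = 0.95, gridLength = 100L) {
  stopifnot(is(series, "PairedSeries"))
  a <- series@valuesA; b <- series@valuesB
  if (length(a) < 10L) stop("need at least 10 pairs")
  d <- a - b
  m <- (a + b) / 2
  if (stats::sd(m) == 0) stop("degenerate x-variance")
  df <- data.frame(m = m, d = d)
  fit <- stats::lm(d ~ m, data = df)
  sm <- summary(fit)$coefficients
  grid <- data.frame(m = seq(min(m), max(m), length.out = gridLength))
  band <- stats::predict(fit, newdata = grid, interval = "prediction",
                         level = level)
  atPoints <- stats::predict(fit, newdata = df, interval = "prediction",
                             level = level)
  eps <- 1e-8 * (1 + max(abs(d)))
  inside <- d >= atPoints[, "lwr"] - eps & d <= atPoints[, "upr"] + eps
  list(slope = sm[2L, 1L], intercept = sm[1L, 1L],
       pSlope = sm[2L, 4L],
       band = data.frame(average = grid$m, fit = band[, "fit"],
                         lwr = band[, "lwr"], upr = band[, "upr"]),
       fractionInside = mean(inside), level = level)
}

#' Assumption checks for the limits-of-agreement analysis
#'
#' Three checks on the paired differences: normality (D'Agostino-Pearson
#' omnibus test), trend (the proportional-bias slope test of difference on
#' average), and heteroscedasticity (slope test of the absolute regression
#' residuals on the average). A check passes when its p-value exceeds
#' `alpha`.
#'
#' @param series a [PairedSeries-class] with n >= 8.
#' @param alpha significance level for the pass/fail flags.
#' @return list of three sublists (`normality`, `trend`,
#'   `heteroscedasticity`), each with `p` and `pass`, plus `degenerate`
#'   flag for zero-variance differences.
#' @export
assumptionChecks <- function(series, alpha = 0.05) {
  stopifnot(is(series, "PairedSeries"))
  a <- series@valuesA; b <- series@valuesB
  if (length(a) < 8L) stop("need at least 8 pairs")
  d <- a - b
  m <- (a + b) / 2
  if (stats::sd(d) == 0)
    return(list(degenerate = TRUE,
                normality = list(p = NA_real_, pass = NA),
                trend = list(p = NA_real_, pass = NA),
                heteroscedasticity = list(p = NA_real_, pass = NA)))
  norm <- dagostinoPearsonTest(d)
  if (stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    pTrend <- summary(fit)$coefficients[2L, 4L]
    pHet <- summary(stats::lm(abs(stats::residuals(fit)) ~ m))$coefficients[2L, 4L]
  } else {
    pTrend <- NA_real_; pHet <- NA_real_
  }
  list(degenerate = FALSE,
       normality = list(p = norm$p.value, pass = norm$p.value > alpha),
       trend = list(p = pTrend, pass = is.na(pTrend) || pTrend > alpha),
       heteroscedasticity = list(p = pHet,
                                 pass = is.na(pHet) || pHet > alpha))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe-Glynn kurtosis
#' test into the omnibus statistic `K2 = Z1^2 + Z2^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2), `p.value`, `z.skewness`,
#'   `z.kurtosis`.
#' @export
dagostinoPearsonTest <- function(x) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations")
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  if (m2 == 0) stop("zero variance")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  ## skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xx * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z.skewness = z1, z.kurtosis = z2)
}

#' Stratified mean/SD summaries of a biometry table
#'
#' Per-group mean and SD for each requested parameter. Groups of size one
#' report SD as NA; empty groups (unused factor levels) are omitted with a
#' warning.
#'
#' @param table data.frame of per-eye parameters.
#' @param by name of the grouping column in `table`.
#' @param params character vector of numeric columns to summarise
#'   (default: all numeric columns).
#' @return data.frame with `group`, `n`, and `<param>_mean`, `<param>_sd`
#'   columns.
#' @export
groupSummaries <- function(table, by, params = NULL) {
  stopifnot(is.data.frame(table), by %in% names(table))
  if (is.null(params))
    params <- names(table)[vapply(table, is.numeric, logical(1L)) &
                             names(table) != by]
  g <- table[[by]]
  if (is.factor(g) && any(!levels(g) %in% unique(as.character(g))))
    warning("empty groups omitted")
  g <- as.character(g)
  groups <- unique(g)
  rows <- lapply(groups, function(lev) {
    sub <- table[g == lev, , drop = FALSE]
    out <- data.frame(group = lev, n = nrow(sub))
    for (p in params) {
      out[[paste0(p, "_mean")]] <- mean(sub[[p]], na.rm = TRUE)
      out[[paste0(p, "_sd")]] <- if (nrow(sub) > 1L)
        stats::sd(sub[[p]], na.rm = TRUE) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Exclusion accounting for a scanned cohort
#'
#' @param nTotal scans acquired.
#' @param nExcluded scans excluded (e.g. scleral spurs not identifiable).
#' @return list with `nTotal`, `nExcluded`, `nRetained` and
#'   `percentRetained`.
#' @export
#' @examples
#' exclusionSummary(1118, 49)$percentRetained
exclusionSummary <- function(nTotal, nExcluded) {
  stopifnot(isCount(nTotal), isCount(nExcluded, min = 0),
            nExcluded <= nTotal)
  list(nTotal = as.integer(nTotal), nExcluded = as.integer(nExcluded),
       nRetained = as.integer(nTotal - nExcluded),
       percentRetained = 100 * (nTotal - nExcluded) / nTotal)
}
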