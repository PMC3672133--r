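---
title: "Semi-automatic anterior-segment OCT biometry: models and methods"
author: "asoct package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic anterior-segment OCT biometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asoct)
```

## What the package does

`asoct` implements a semi-automatic analysis of anterior-segment optical
coherence tomography (AS-OCT) horizontal B-scans. The only manual input is
the pixel position of the two scleral spurs; from there the pipeline is
fully deterministic:

1. **Binarization** — a 3x3 median filter suppresses speckle, an intensity
   threshold calculated from the image histogram (Otsu's between-class
   variance criterion) converts the 8-bit scan into 1s (tissue) and 0s
   (open space).
2. **Edge extraction** — a column-wise run rule locates boundaries: a row
   is an anterior-surface point when the 5 pixels strictly above it are
   all 0 and the 5 pixels from it downward are all 1; the inverted rule
   finds posterior (tissue-to-open) boundaries. The first qualifying row
   per column wins; columns without a qualifying row stay missing.
3. **Smoothing and fitting** — each raw border is repaired with a running
   median, fitted with a polynomial, pruned of outliers, and refitted
   once.
4. **Biometry** — central corneal thickness (CCT, um), aqueous depth and
   anterior chamber depth (ACD, mm; `acd = aqueous + cct/1000`, matching
   optical-biometer convention), corneal radii from circle fits, and the
   keratometry reading `K = 1000*(n_k - 1)/r` with the clinical
   keratometric index `n_k = 1.3375`.
5. **Agreement statistics** — Bland-Altman mean difference, SD, 95%
   limits of agreement (LOA = mean difference +/- 1.96 SD) with
   confidence intervals, percentage bias (mean difference over the grand
   mean), paired t-test, Pearson correlation, and difference-on-average
   regression with a 95% prediction band (the proportional-bias check).

Because no public image set accompanies this class of analysis, the
package also contains a first-class synthetic-data module: a phantom
renderer with exact analytic ground truth and a paired-cohort simulator
with a controllable constant or proportional bias structure. Every
downstream stage is tested against these generators.

## The phantom model

An eye is described by `AnteriorSegmentGeometry`: two circular corneal
arcs sharing the central axis (anterior radius default 7.2 mm, posterior
0.89 x anterior), apex thickness (560 um), an iris plane with a circular
pupil aperture (radius 2 mm), an anterior lens arc (radius 10 mm) whose
apex sits `aqueousDepth` (2.73 mm) behind the posterior corneal apex, and
a scleral shell that continues the anterior arc laterally beyond the two
scleral spurs (at +/- 6 mm). The defaults reproduce a population-typical
adult eye: ACD 3.29 mm, CCT 560 um, K about 46.9 D.

The renderer maps this geometry onto a 600 x 300 pixel raster covering a
16 x 6 mm field of view (26.67 um lateral, 20 um axial per pixel), with
row 0 anterior, 0-based indices and pixel centres at integer coordinates.
The axial extent of the instrument class's raster is not standardised, so
the field of view is a documented assumption and fully configurable.
Tissue regions are half-open in depth (`[upper, lower)`), which makes the
rasterisation convention exact: the first tissue row of a column is
`ceiling(y)` for a surface crossing at row `y`. The analytic curves,
sampled per column in pixel coordinates, are returned as ground truth.

Noise is multiplicative gamma speckle (shape 4, i.e. relative SD 0.5,
the dominant corruption of coherent imaging) followed by additive
Gaussian read noise (SD 8 intensity units) and optional salt-and-pepper
dropouts, clipped to 8 bits — a minimal OCT-like corruption that
genuinely stresses thresholding without defeating it. The generator never
models refraction-induced distortion, depth-dependent attenuation,
motion, or wave-optics speckle correlation; passing tests therefore
demonstrate correctness of the *algorithms*, not clinical performance on
real scans.

### Simulated paired cohorts

`simulateCohort` draws truth `t ~ N(trueMean, trueSd)` and returns
modality A = `t + e_A` and modality B =
`t + biasIntercept + biasSlope*t + e_B` with independent
`e ~ N(0, noiseSdEach)`. Three pre-calibrated specs mirror the agreement
structure the statistics module is designed for:

* `acdCohortSpec()` / `cctCohortSpec()` — constant bias (slope 0), with
  `noiseSdEach = sdDiff/sqrt(2)` so the difference SD matches its target
  (0.16 (0.20) mm and 16.75 (17.35) um respectively) and `trueSd` set to
  match the reference-modality SD. With equal per-modality noise the
  model cannot also match the second modality's SD exactly; the
  reference SD was chosen as the anchor.
* `kReadingCohortSpec()` — proportional bias. Matching both modality
  means/SDs (43.98/1.53 vs 46.79/2.72) *and* their correlation (0.50)
  under equal noise forces, in closed form (`calibrateCohortSpec`),
  `biasSlope ~ 1.79` and a large negative intercept. The parameters are
  not a physical claim about either instrument; they are the unique
  equal-noise generating model reproducing every observable, including
  the difference SD (2.36 D) and a difference-on-average slope of about
  0.73.

## Numerical choices that matter

**Threshold.** The source software "progressively tailors" its contrast
threshold; the exact rule is unpublished. Otsu's criterion is the
deterministic stand-in: it is parameter-free, reproducible, and the
`computeThreshold`/`binarize` seam makes it swappable. A single 3x3
median-filter pass (configurable, including off) precedes thresholding;
without it, shape-4 speckle drops roughly a fifth of tissue pixels below
any global threshold and the 5-consecutive-pixels rule fails on most
columns. The filter is a vectorised median-of-9 selection network, so it
costs a few whole-matrix min/max operations.

**Edge rule conventions.** "5 above / 5 below" is read as 5 strictly
above and 5 at-and-below the candidate row; ties break topmost; the
posterior and iris rules reuse the same pattern with inverted polarity
(the anterior rule is the only one stated by the method's description —
the symmetric extension is ours). Columns within 5 px of the lateral
borders are never scanned. The run context is read from the full image;
the search band only restricts candidate rows.

**Sub-pixel refinement.** Detected rows are integers, and the staircase
they form is systematically flat around the corneal apex: a circle fit to
it can misestimate the radius by up to ~1 D at adversarial quantization
phases. A detected row `d` certifies the boundary lies in `(d-1, d]`, and
wherever the (smoothed, outlier-pruned) staircase steps by one row the
boundary crosses that integer level near the column midpoint.
`smoothAndFit` therefore refits its polynomial to these level-crossing
points (falling back to interval midpoints `d - 0.5` for flat borders
such as the iris plane). Continuous, non-integer inputs bypass this and
are fitted literally.

**Polynomial degrees and fit chord.** Degree 4 for the corneal surfaces,
degree 2 for iris and lens; running-median window 11; outlier tolerance
3 px with a single refit. Corneal fits use an 8-mm chord centred on the
spur midline: wide enough to pin the quartic's apex curvature, narrow
enough that the degree-4 truncation error of a circular arc stays below
one tenth of an axial pixel across the sampled radius range.

**Curvature zone.** The clinical keratometry zone is the central 3 mm,
and `fitCurvature(zone = 3)` provides it. It is *not* the default: with
20 um axial pixels a 3-mm chord has only ~8 px of sagitta, and the
quantized data fundamentally cannot resolve the radius to the ~0.04 mm
that 0.25 D corresponds to. The default zone is therefore the full
corneal fitting chord. For the circular phantoms the two choices estimate
the same quantity; for a real (aspheric) cornea the full-chord radius is
a flatter average, which is the documented trade-off.

**Circle fit.** Algebraic Kasa fit via 3x3 normal equations, then one
Gauss-Newton step on the geometric residuals; degenerate (collinear)
input or a radius above 1e4 mm is flagged `"flat"` instead of erroring.

**Iris/lens separation.** The deep open-to-tissue search between the
spurs sees three populations: the iris plane, the lens apex through the
pupil, and peripheral echoes of the anterior surface where the globe
curves away. Echoes are removed by comparing against the anterior
detection in the same column; the pupil is the contiguous run around the
spur midline bounded by an adjacent-column depth jump above 6 px (on a
median-filtered sequence, tolerating up to 5 missing columns); what
remains within 8 px of the iris median depth forms the iris trace. The
generator keeps the iris plane 0.23 mm anterior to the lens apex so this
jump is resolvable by construction.

**Agreement details.** The difference direction is fixed as device minus
reference, matching the positive biases the analysis is designed around.
CI of the LOA uses the classic large-sample SE `sd*sqrt(3/n)`; printed
tables round half away from zero at 2 decimals. The normality check is
the D'Agostino-Pearson omnibus test, written out from the published
skewness/kurtosis approximations because no installed package provides
it (it reproduces an independent reference implementation to 1e-10 in
the test suite). Heteroscedasticity is checked by regressing absolute
residuals on the average.

**Degenerate inputs.** Constant images are a threshold error
("degenerate histogram"); identical paired series yield NA correlation
with a QC flag rather than an exception; a missing lens trace yields NA
ACD with a QC flag; scans whose spurs are not identifiable are excluded
and counted, never silently dropped.

## What the test suite establishes

Unit tests pin each operation to an independent oracle: exhaustive
256-way threshold scans, naive per-column edge scans, first-principles
Bland-Altman recomputation from explicit sums, and frozen external
reference values for the normality test. Property tests cover
determinism, threshold monotonicity, translation equivariance of the
edge rule, LOA algebra, swap antisymmetry, and the exact
`acd = aqueous + cct/1000` identity.

End-to-end, the pipeline is required to recover generator ground truth
on 100 noise-free phantoms spanning CCT 480-640 um, ACD 2.6-4.0 mm and
anterior radius 6.5-8.5 mm to within 1 axial pixel (20 um / 0.02 mm) for
CCT and ACD and 0.25 D for K, and on 50 default-noise phantoms to within
2 px / 0.75 D at the 95th percentile. Statistical calibration is checked
by simulation: within-LOA coverage of difference cohorts, ~5% type-I
error of the proportional-bias slope test on slope-0 cohorts, and >= 90%
power at the calibrated proportional-bias magnitude (all problem sizes
as stated in the tests, chosen to keep the suite fast while leaving
Monte-Carlo error well inside the asserted margins).

Under default speckle the thresholded tissue mask erodes slightly, so
CCT reads systematically thin by roughly half a pixel equivalent —
within stated tolerances, and an honest property of threshold-based
segmentation worth remembering when comparing against contact
pachymetry.

## Known limitations

* The renderer's eye is axially symmetric; astigmatism, decentration
  beyond a lateral shift, corneal asphericity and lens tilt are not
  modelled.
* Automatic scleral-spur detection is out of scope by design — the
  method is deliberately semi-automatic.
* Angle metrics (AOD, TISA, trabecular-iris angle) are not computed.
* No dewarping/refraction correction is applied; measurements are taken
  in raster space scaled by the stated pixel pitch, as in the software
  being modelled.
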