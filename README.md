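# asoct

Semi-automatic anterior-segment biometry from AS-OCT B-scans, with the
method-comparison statistics used to validate such measurements against
standard clinical instruments — plus a synthetic phantom generator that
makes the whole pipeline testable without any imaging data.

## The problem

Anterior-segment optical coherence tomography produces cross-sectional
(B-scan) images of the front of the eye, but extracting clinical numbers
from them — central corneal thickness (CCT), anterior chamber depth
(ACD), keratometry (K) — traditionally relies on manually placed
calipers. Semi-automatic software reduces the manual input to a single
landmark pair: the two scleral spurs. This package implements that
analysis style end to end for 8-bit grayscale horizontal B-scans
(nominally 300 rows x 600 columns):

* **Segmentation** — calculated threshold (Otsu on the histogram, after
  a 3x3 median speckle filter) -> binary tissue/open-space copy ->
  column-wise edge rule (5 consecutive 0s above and 5 consecutive 1s
  below mark an anterior surface point; inverted for posterior
  surfaces) -> running-median smoothing and polynomial fits for the
  corneal epithelium, endothelium, anterior iris and anterior lens.
* **Biometry** — CCT as the fitted epithelium-to-endothelium distance at
  the corneal apex; ACD as the aqueous depth (posterior cornea to lens)
  plus CCT, `acd = aqueous + cct/1000`; corneal radii by least-squares
  circle fits (Kasa + one Gauss-Newton step); `K = 1000(n_k - 1)/r` with
  the keratometric index `n_k = 1.3375`.
* **Agreement** — Bland-Altman analysis of paired measurements: mean
  difference `d` and SD `s`, 95% limits of agreement `d ± 1.96 s` with
  confidence intervals (`SE = s * sqrt(3/n)`), bias percentage
  `100 d / mean`, paired t-test, Pearson r, and difference-on-average
  regression with a 95% prediction band to detect proportional bias.
* **Synthetic data** — phantom eyes (corneal arcs, iris plane with pupil
  aperture, lens cap, scleral shell, gamma speckle) rendered with exact
  analytic ground truth, and paired cohorts simulated with constant or
  proportional bias structure.

## Worked example

```r
library(asoct)

## a phantom eye with known geometry, rendered noise-free
ph  <- renderBScan(AnteriorSegmentGeometry(), noiseFree())
img <- bscanImage(ph)

## segment (seeded by the two scleral spurs) and measure
bounds <- segmentBScan(img, spurs(ph))
measureBiometry(bounds, 16/600, 6/300, imageId = "phantom")
#> OcularBiometry 'phantom':
#>   CCT 561.5 um | aqueous 2.727 mm | ACD 3.289 mm
#>   R ant 7.208 mm | R post 6.421 mm | K 46.82 D
```

The generating truth was CCT 560 um, aqueous 2.73 mm, ACD 3.29 mm,
anterior radius 7.2 mm (K 46.875 D): every parameter is recovered well
within one axial pixel (20 um) and 0.25 D.

```r
## agreement between a simulated device and reference instrument:
## constant bias 0.16 mm, difference SD 0.20 mm, n = 1069
co  <- simulateCohort(acdCohortSpec(seed = 1))
res <- blandAltman(PairedSeries(co$modalityB, co$modalityA,
                                labels = c("AS-OCT", "optical biometer"),
                                unit = "mm"))
res
#> Bland-Altman agreement: AS-OCT vs optical biometer (mm), n = 1069
#>   mean diff 0.1709 (SD 0.2084), bias 5.33%
#>   95% LOA (-0.2375, 0.5793); CI lower (-0.2592, -0.2159), upper (0.5577, 0.6009)
#>   r = 0.860; diff-on-average slope -0.0135 (p = 0.422); coverage 95.4%
```

The device measures deeper chambers by 0.17 mm on average in this draw
(the generating bias was 0.16 mm); 95.4% of the paired differences fall
inside the limits of agreement, and the non-significant
difference-on-average slope correctly reports the absence of
proportional bias. `agreementTable(res)` formats the same result as a
publication-style comparison row; `blandAltmanPlot(...)` draws it.

`runPipeline(outDir, n = 20, seed = 1)` chains everything: renders a
phantom cohort, segments and measures every scan whose spurs are marked
visible (the rest are counted in `exclusions.csv`), compares the
measurements against the generator's ground truth, and writes biometry
and agreement CSV/JSON artifacts, plots, and a run manifest.

See the methods vignette (`vignettes/asoct-methods.Rmd`) for the model,
the numerical conventions (sub-pixel boundary refinement, curvature
zone, rounding), and known limitations.

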