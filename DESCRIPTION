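Package: asoct
Title: Anterior Segment OCT Phantom Simulation, Boundary Segmentation,
    Biometry and Instrument Agreement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic analysis of anterior-segment optical coherence
    tomography (AS-OCT) horizontal B-scans. Renders synthetic anterior-segment
    phantoms (corneal arcs, iris plane with pupil aperture, anterior lens
    surface, scleral shell, speckle noise) with exact analytic ground truth;
    segments tissue boundaries from 8-bit grayscale scans by calculated-threshold
    binarization, column-wise consecutive-pixel edge rules seeded by two
    observer-marked scleral spurs, running-median smoothing and polynomial
    fitting; derives central corneal thickness, anterior chamber depth and
    keratometry from the fitted boundaries; and quantifies between-instrument
    agreement with Bland-Altman limits of agreement, their confidence
    intervals, percentage bias, and difference-on-average proportional-bias
    regression with prediction bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
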