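Package: pectinmap
Title: Hyperspectral Imaging Chemometrics for Pixel-Wise Pectin Mapping
    in Fruit Flesh
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and visualization pipeline for predicting pectin
    content (protopectin, water-soluble pectin, total pectin, mg/g) in
    fruit-flesh cross-sections from reflectance hypercubes.  Provides an
    ENVI/BIL hypercube reader and writer with white/dark reflectance
    correction, ROI segmentation and slice-level mean-spectrum extraction,
    standard normal variate and Savitzky-Golay preprocessing, partial least
    squares regression (NIPALS) and least squares support vector machine
    calibration under full leave-one-out cross-validation, wavelength
    selection by the successive projections algorithm (SPA), uninformative
    variable elimination (UVE), the UVE-SPA cascade and competitive adaptive
    reweighted sampling (CARS), model-grid evaluation with RMSEC, RMSECV,
    correlation, RPD and AB_RMSE metrics, and pixel-wise pseudo-color
    distribution maps.  A synthetic scene generator produces hypercubes with
    known per-pixel concentration ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
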