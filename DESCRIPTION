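Package: pmjcsa
Title: Pontomedullary Junction-Referenced Spinal Cord Cross-Sectional Area
    Morphometry and Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures spinal cord cross-sectional area (CSA) from binary
    cord segmentations using a neurological reference: the distance along
    the cord centerline from the pontomedullary junction (PMJ). Provides
    centerline extraction with arc-length parameterization, slice-wise
    angulation-corrected CSA, a mirrored cross-correlation search for the
    right-left symmetry slice, vertebral-level CSA for comparison, and a
    regression-residual normalization family (published coefficient sets,
    refitting, stepwise predictor selection, z-scores, coefficient of
    variation). Includes synthetic tube phantoms with analytically known
    geometry and a cohort simulator with a known generative linear model
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
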