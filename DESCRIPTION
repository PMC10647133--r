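Package: phytochroma
Title: Colour-Checker Correction, Object Measurement and Pigment
    Estimation for Plant Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An image-analysis pipeline for quantitative plant phenotyping
    from consumer-camera photographs. Images taken on a white background
    with a 24-swatch colour checker are flat-field corrected against a
    background exposure, colour corrected by per-channel third-order
    polynomial regression on the checker swatches, segmented by colour
    thresholding and morphological cleanup, and measured: each detected
    object's physical width, height and area (calibrated against a
    reference object of known size) and its mean colour in RGB, YUV
    (BT.601 full range) and CIELAB (D65, 2 degree observer). Exponential
    calibration models link colour to pigment content: lycopene from the
    CIELAB a*/b* ratio and total chlorophyll from mean RGB, with
    spectrophotometric ground-truth formulas, nonlinear and log-linear
    fitting, prediction with extrapolation flagging, and validation
    statistics. A deterministic synthetic-scene generator renders
    checker-plus-object images with ground truth so the whole pipeline is
    testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
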