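Package: vitrophen
Title: Multi-Sensor Phenotyping of Plant In Vitro Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing toolkit for automated multi-sensor phenotyping of
    plant in vitro cultures grown in closed vessels. Implements the full
    desk-scale analysis chain: pixel-metric and laser distance calibration,
    spectrometer detection-spot-size determination, trainable random-forest
    RGB segmentation with trait extraction (projected area, solidity,
    stockiness, degree of coverage), depth-scan processing with Hough circle
    medium detection and RANSAC plane segmentation yielding medium height and
    volume plus canopy height metrics, chlorophyll fluorescence spectrum
    processing (dark-current subtraction, F690/F730/F740 indices), thermal
    frame conversion, optical haze index arithmetic, and the validation
    statistics used to characterise such systems (confusion statistics,
    adjusted R-squared regression reports, repositioning repeatability). A
    synthetic vessel-scene generator with exact ground truth replaces the
    hardware so that every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
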