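Package: noscolor
Title: Structural-Color Modelling and Colorimetric Separation Statistics
    for Nanocavity-on-Silicon Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-models the structural color of tissue sections mounted
    on nanocavity-on-silicon (NOS) slides via transfer-matrix thin-film
    reflectance and CIE 1931/CIELAB colorimetry, quantifies the separation
    of healthy and cancerous CIELAB point clouds with kernel-density
    intersection-over-union, Frobenius norm and Chamfer distance, and
    evaluates diagnostic agreement (Cohen's kappa, consistency rate) and
    classifier performance (confusion-matrix metrics, ROC, AUC). A seeded
    synthetic tissue-section generator renders refractive-index and
    thickness fields to RGB through the same optical model so the whole
    analysis runs end-to-end without real slide images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
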