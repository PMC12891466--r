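Package: ecgdigitizer
Title: Digitization of Paper ECGs into Calibrated Multi-Lead Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts scanned or photographed paper electrocardiograms into
    calibrated multi-lead time series. The pipeline combines semantic
    segmentation with a residual U-Net, perspective correction through a
    two-stage Hough (angle-radius then angle-angle) analysis of the detected
    grid, autocorrelation-based grid-spacing calibration, lead-layout
    identification from segmented lead-name markers, and conversion of the
    segmented trace pixels into per-lead voltage series with explicit missing
    value semantics. A synthetic paper-ECG generator with pixel-accurate
    ground truth supports training and end-to-end evaluation, and a shifted
    signal-to-noise-ratio harness scores reconstructions against reference
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
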