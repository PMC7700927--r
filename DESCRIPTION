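Package: gammaQC
Title: Automated Quantitative Phantom Analysis for Gamma Camera and SPECT Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, quantitative analysis of standard nuclear-medicine quality-control
    phantoms. Implements standard-deviation-based modulation transfer function (MTF)
    estimation for four-quadrant bar phantoms, and cold-sphere contrast-to-noise,
    cold-rod modulation and uniformity percent-deviation analysis for ACR/Jaszczak-style
    SPECT phantoms, with automatic phantom detection and template-driven region-of-interest
    placement. Includes a synthetic phantom simulator with known ground truth, a minimal
    DICOM reader/writer for uncompressed single-frame images, longitudinal control-chart
    (mean plus/minus three sigma) trending, and worksheet pass/fail evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
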