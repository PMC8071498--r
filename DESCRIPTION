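Package: argmark
Title: Colorimetric Quantification of Arginine in Latent Fingermark Deposits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for colorimetric (Sakaguchi) arginine
    assays read out from scanned detection-window images. Implements the
    red-to-magenta channel-substitution tint, RGB to HSB conversion and
    mean-saturation measurement over a segmented window, linear calibration
    against a standard series with inverse prediction of concentration, and
    donor-level aggregation with biological-sex classification and cohort
    statistics. A synthetic forward model renders detection-window images
    from known concentrations and simulates donor cohorts so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
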