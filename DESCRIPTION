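Package: microcensus
Title: Motion-Based Background Removal for Counting and Measuring
    Organisms in Laboratory Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a still-background image from a stack of co-registered
    frames of a fixed scene (minimum, maximum, median or mean Z-projection),
    removes it from each frame to reveal the moving organisms, then
    thresholds, labels, counts and measures the resulting particles in
    physical units. Includes region-of-interest and physical-scale
    calibration, population census summaries (per-frame counts, biosurface,
    size distributions, regression-based density correction at high
    density), sliding-window backgrounds for long time-lapses,
    single-organism trajectory extraction, activity time series, recursive
    batch processing of replicated microcosm boxes, and a seeded synthetic
    scene generator with full ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    png,
    tiff,
    jpeg,
    yaml,
    mgcv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
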