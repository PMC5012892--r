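Package: phagoquant
Title: Quantification of Live-Cell Phagocytosis Assays from Time-Lapse Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for plate-based macrophage phagocytosis
    assays with pH-sensitive (pHrodo-style) bioparticles imaged on live-cell
    time-lapse platforms. Per-frame processing applies white top-hat background
    non-uniformity correction with a disk structuring element, fixed
    thresholding in corrected intensity units, 8-connected object labeling,
    marker-controlled watershed declumping of closely spaced objects, and an
    area filter in square micrometres; phase-contrast frames yield a
    texture-based confluence mask. Per-well kinetic curves are summarised by a
    max-normalised rising-phase slope, trapezoidal area under the curve,
    fold change and percent-of-vehicle normalisation, and peak/plateau phase
    detection. A seeded stochastic plate simulator renders synthetic
    time-lapse image stacks with event-level ground truth (Poisson engulfment
    with saturating concentration dependence and an exponential acidification
    lag) for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
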