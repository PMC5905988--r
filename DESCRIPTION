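Package: vesselcaliber
Title: Retinal Blood Vessel Caliber Estimation by Parametric Profile Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the caliber (diameter, in pixels) of retinal blood
    vessels in eye fundus images. Starting from a binary vessel segmentation
    mask, one-pixel-wide centerline segments are extracted by morphological
    thinning, smoothed with least-squares cubic splines, and cross-section
    intensity profiles are sampled along the centerline normals on the green
    channel. Profile extents are detected with peak-search rules that handle
    the central light reflex, and profiles are fitted with parametric models
    (an adapted Hermite model and two Difference-of-Gaussians-times-line
    models) by bounded nonlinear least squares. Vessel width is estimated
    from the best-fit parameters with ensembles of bagged regression trees,
    and precision is evaluated with cross-validation and
    leave-one-segment-out schemes. A synthetic vessel image generator with
    exact ground-truth edges supports development and testing without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
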