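Package: algrow
Title: Single-Cell Growth Analysis for Surface-Attached Microalgae from
    Time-Lapse Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the growth of individual surface-attached
    microalgal cells (e.g. Scenedesmus) imaged in a parallel-plate flow
    chamber under controlled hydraulic shear. Provides a synthetic micrograph
    generator with full ground truth, a shallow feed-forward pixel classifier
    trained by Levenberg-Marquardt optimisation for cell/background
    segmentation, connected-component cell detection with moment-based
    ellipse fitting, pixel-to-micrometre calibration and 2D-to-3D volume
    estimation, nearest-centroid tracking with division and loss events,
    exponential smoothing and cubic growth-curve fitting of per-cell volume
    series, and per-flow-rate aggregation of growth metrics including a
    flow-rate to energy-dissipation-rate lookup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    knitr,
    nnet,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
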