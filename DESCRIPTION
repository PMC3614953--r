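Package: pathcurve
Title: Path-Curve Shape Analysis of Plant Organ Outlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits two-dimensional path curves (projective-geometry egg forms
    parameterized by the shape parameter lambda) to photographed plant-organ
    silhouettes such as mistletoe berries and tree buds. A photograph is
    thresholded to a binary silhouette, its outline is traced, and an exact
    Euclidean distance transform turns curve-to-contour congruence into a
    least-squares energy that a staged hill-climbing search minimizes over six
    curve parameters. Around the fitter the package provides a blinded,
    randomized batch-measurement workflow with EXIF capture-time extraction
    and append-only CSV records, circadian rhythm statistics (per-day
    normalization, hourly profiles with standard errors, LOWESS smoothing,
    operator-pair Pearson correlations), and a ground-truthed synthetic berry
    image and time-series generator that makes the whole pipeline testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jpeg,
    png,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
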