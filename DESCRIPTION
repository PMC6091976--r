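Package: morphospec
Title: Spectral Profiling of Cellular Morphodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell-edge morphodynamics from segmented
    time-lapse movies. Cell outlines are extracted per frame, virtual edge
    markers are mapped between consecutive frames by minimizing displacement
    plus lateral strain, and signed normal edge velocities are compiled into
    protrusion activity maps. The maps are decomposed row- and column-wise by
    empirical mode decomposition and the Hilbert transform into instantaneous
    frequency and amplitude spectra, which are compared between cells with
    Kolmogorov-Smirnov statistics, clustered into motion regimens by
    statistical region merging, and related to windowed biosensor activity by
    lagged cross-correlation. A synthetic-data generator with analytic ground
    truth supports end-to-end validation.
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
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
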