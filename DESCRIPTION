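Package: vesiclebridges
Title: Geometry, Simulation and Statistics of Inter-Vesicle Bridges in
    Presynaptic Terminals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the short filamentous bridges that
    connect neighboring synaptic vesicles in electron tomograms of
    presynaptic terminals. Provides vesicle-cloud containers and
    deterministic pair geometry (normalized surface separations, Z-angles,
    neighbor counts, volumetric fractions), hard-sphere simulations of
    vesicle clouds built from chains of bridged vesicles with
    fixation-shrinkage and expansion transforms, rendering of synthetic
    tomogram-like volumes with missing-wedge degradation and rotated
    averaged pair views, blinded randomized pair-survey manifests with
    score ingestion, and the bridge statistics: per-tomogram bridge
    probabilities, the chain-link model, Wilson score intervals with
    continuity correction, Yates-corrected chi-square and
    Kolmogorov-Smirnov tests, separation histograms, docked-distance
    profiles, and overlap-after-expansion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
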