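Package: meadev
Title: Spike, Burst and Longitudinal Activity Analysis for Multiwell
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity recorded from
    developing neuronal cultures on multiwell microelectrode arrays (MEA).
    Provides adaptive-threshold spike detection (threshold at a multiple of
    the baseline noise standard deviation), max-interval single-electrode
    burst detection, overlap-based network-burst detection, per-electrode
    and well-averaged activity features, a penalized-spline gamma
    generalized additive model for comparing developmental trajectories
    between genotypes, and a zero-inflated beta regression model with
    batch random intercepts for bounded proportion assays. A synthetic-data
    module simulates two-genotype culture plates with known ground truth so
    every stage of the pipeline can be validated without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
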