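Package: hippoSCN
Title: Hippocampal Structural Covariance Networks and Intrusive-Memory Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of anterior/posterior hippocampus
    structural covariance in relation to ecological-momentary-assessment
    (EMA) counts of trauma-related intrusive memories. Provides a synthetic
    cohort generator with a planted latent covariance structure,
    probabilistic subregion templates with longitudinal-axis cuts,
    gray-matter morphometry (seed densities, subregion volumes, analysis
    masks, Gaussian smoothing), seed-based non-rotated partial least squares
    with permutation and bootstrap-ratio inference, cluster extraction from
    bootstrap-ratio maps, and offset Poisson regression of EMA count
    outcomes with Nagelkerke pseudo-R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
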