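Package: pfclust
Title: Spatial Clustering Analysis of Sensory-Evoked Parallel Fibre Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Analysis pipeline for inferring micron-scale spatial clustering
    of sensory-activated cerebellar parallel fibre axons from in vivo calcium
    imaging. Provides calcium-event detection on fluorescence traces with a
    varying-baseline threshold, stimulus-locked response classification,
    burst decomposition from high-rate linescans, a binomial null model for
    fibre co-activation with a chi-square goodness-of-fit test,
    nearest-neighbour-distance Monte Carlo tests of complete spatial
    randomness, trial-to-trial coupling analysis of binary response rasters,
    labelling-density calibration from bouton maps, and a ground-truthed
    synthetic-data generator emulating the statistical structure of sparse
    parallel fibre recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    mclust,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
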