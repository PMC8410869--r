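Package: plankdiv
Title: Ensemble Species Distribution Modelling of Plankton Diversity Under
    Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for estimating present and
    future marine plankton species richness, community turnover,
    species-association networks and climate-impact severity from species
    occurrence records and gridded monthly environmental climatologies.
    Provides a synthetic-world generator (gridded environments with a
    latitudinal temperature gradient and seasonality, virtual species with
    unimodal niches, biased sampling effort, pseudo earth-system-model
    anomalies), record-level quality control and monthly grid binning,
    derived-predictor computation with collinearity screening, target-group
    pseudo-absence selection with environmental stratification, an ensemble
    of four species distribution model families (GLM, GAM, random forest,
    neural network) with repeated split-sample evaluation, delta-method
    climate projection, habitat-suitability stacking into potential species
    richness, Jaccard turnover/nestedness partitioning, signed
    log-likelihood-ratio co-occurrence scoring, MESS extrapolation
    detection, metabolic-theory temperature-richness fits, range-shift
    velocities, severity regionalisation and ecosystem-service overlap
    tests. All user-facing functions take and return data frames so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    mgcv,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
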