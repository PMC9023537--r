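Package: aerialsdm
Title: Species Distribution Models from Dual-Observer Aerial Line-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible pipeline for modeling marine
    megafauna distributions from aerial line-transect surveys. Converts
    clinometer sighting angles to perpendicular distances, fits
    multiple-covariate (MCDS) and dual-observer mark-recapture (MRDS, point
    independence) detection functions with AIC selection, derives effective
    search effort, grids sightings, effort and environmental covariates
    (including daily-maximum-standardized SST frontal gradients) to a 10-km
    cell-by-day table, fits effort-offset binomial GAMs over all admissible
    covariate subsets with collinearity screening and tiered significance
    pruning, predicts depth-masked probability-of-occurrence surfaces with
    standard errors, combines surveys by (1-SE)-weighted ensembling or pooled
    refitting, validates internally (k-fold AUC) and externally
    (median-normalized score with a one-sample t-test), and analyzes monthly
    weighted latitudinal centroids with seasonal ARIMA fits and forecasts. A
    synthetic-data module simulates environments with seasonal SST cycles and
    sharp fronts, a known occurrence model, and dual-team surveys with
    imperfect distance-dependent detection, so every stage is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    mgcv,
    pROC,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
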