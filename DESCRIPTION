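Package: deprivmap
Title: Bayesian Identification of Deprived Urban Areas from Census and
    Remote-Sensing Predictors
Version: 0.1.0
Authors@R:
    person("Pathway", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Small-area mapping of deprived ("slum") urban neighbourhoods
    from census microdata and satellite-derived rasters. Builds
    enumeration-area (EA) level predictor matrices (household-category
    proportions, crowding, population density, NDVI zonal means, buffered
    elevation differences), fits Bayesian logistic models with normal,
    lasso (double-exponential) or ridge coefficient priors and optional
    neighbourhood random effects by slice-sampling MCMC, selects models by
    hold-out cross-validation and WAIC, produces posterior-predictive
    probability maps with quintile population summaries and contiguous
    high-probability clusters, and runs local/global Moran's I (LISA)
    permutation analyses. Includes a synthetic-data generator emulating an
    urban EA lattice so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    yaml
Config/testthat/edition: 3
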