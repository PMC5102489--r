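Package: oncatools
Title: Predator, Prey and Habitat Structure Monitoring for Neotropical Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit linking presence-only habitat suitability
    modelling of an apex predator (maximum-entropy model with a null-model AUC
    significance test), closed-population capture-recapture density estimation
    from camera traps (M0 and Burnham-Overton jackknife Mh estimators with
    MMDM-buffered effective survey areas), line-transect kilometric abundance
    and biomass indices with effort-sufficiency diagnostics, and remote-sensing
    habitat-structure proxies (focal-window canopy roughness, LiDAR waveform
    extent). A synthetic-landscape generator with known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    randomForest,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
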