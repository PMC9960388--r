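Package: cnlri
Title: Retention-Index Prediction from Cumulative Neutral Losses in
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts reversed-phase liquid-chromatography retention
    indices of structurally unknown chemicals directly from
    high-resolution tandem mass spectra.  Spectra are converted to
    cumulative neutral losses (precursor mass minus fragment mass) and
    encoded on a ternary 0.01 Da grid spanning 0-1000 Da; a
    descriptor-based quantitative structure-retention relationship model
    pseudo-labels a spectral corpus inside its leverage-based
    applicability domain, and a gradient-boosted-tree regressor is then
    trained on the combined cumulative-neutral-loss features.  Includes
    MSP/MGF readers, descriptor curation (min-max scaling and
    replicate-stability variance filtering), leverage applicability
    domain with leave-one-out thresholds, stratified splitting,
    cross-validation, evaluation metrics, a synthetic-world generator
    for end-to-end testing, and ggplot2 diagnostics.
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
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
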