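Package: hpvSDM
Title: Historical Proximity Variables for Invasive Species Distribution Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds historical proximity variables (HPV) - presence, count and
    distance-to-nearest-site rasters derived from dated occurrence records -
    and uses them as predictors in ensemble species distribution models of
    spreading invasive species. Provides grid geometry and point
    rasterization on a regular lon/lat grid, a factorial enumeration of HPV
    predictor-set variants (information capacity x time period), seven
    single-model algorithms evaluated with the true skill statistic (TSS) and
    ROC, TSS-gated ensemble construction with six combination statistics, a
    shadow-feature (Boruta-style) random-forest meta-model of what drives
    model quality, and HPV-substitution projection scenarios (short-term
    forecast, potential range, site-emergence and unsaturation maps). A
    dispersal-limited invasion simulator generates dated occurrence data and
    spatially autocorrelated environmental landscapes so the whole pipeline
    can be exercised and tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    rpart,
    nnet,
    MASS,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
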