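Package: rattanSDM
Title: Ensemble Species Distribution Modeling for Presence-Background Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible presence-background species distribution modeling
    workflow for data-limited tropical taxa such as Southeast Asian rattans:
    occurrence record cleaning and grid-resolution thinning, spatially
    constrained pseudo-absence design, iterative variance-inflation-factor
    predictor screening, four-family model fitting (logistic GLM,
    penalized-spline GAM, elastic-net logistic regression, random forest),
    replicated and spatially blocked evaluation with null-model significance
    testing, TSS-weighted ensemble prediction, habitat classification with
    latitude-corrected area accounting, and land-cover anthropogenic-pressure
    overlay. Includes a virtual-species simulator (spatially autocorrelated
    environmental fields, known niches, suitability-proportional sampling,
    clustered land cover) so every stage is verifiable without external
    raster or occurrence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    randomForest,
    geosphere,
    multcomp,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
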