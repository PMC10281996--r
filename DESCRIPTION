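Package: shaderange
Title: Ensemble Species Distribution Modelling for Cocoa Agroforestry Shade Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for assessing climate-change
    vulnerability of cocoa and its agroforestry shade-tree species with
    consensus species distribution models. Provides occurrence quality
    control (coordinate, land, collection-year, marginal-climate and source
    filters, grid thinning, minimum-sample rule), buffered pseudo-absence
    sampling, collinearity-based predictor selection (iterative VIF and
    pairwise Pearson filtering), a four-algorithm AUC-weighted ensemble
    (GLM, GAM, boosted trees, random forest) with fourfold cross-validation,
    TSS-optimal binarization, scenario projection with land-cover-constrained
    suitable-area accounting, and shade-species richness and hotspot mapping.
    A synthetic-data module generates spatially autocorrelated environmental
    stacks, virtual species with known niches, contaminated occurrence
    samples, shifted future scenarios and land-cover rasters so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    mgcv,
    randomForest,
    xgboost,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
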