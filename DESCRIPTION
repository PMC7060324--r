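Package: agropls
Title: Multi-Response PLS with VIP Selection for Farm Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating farm survey and soil data to crop performance
    indicators with multi-response partial least squares (PLS) regression.
    Implements NIPALS PLS2 on centered, unit-variance-scaled matrices,
    cross-validated predictive ability (Q2Y via PRESS), variable importance
    in the projection (VIP) with the VIP >= 1 filter-and-refit workflow,
    relative prediction error (RMSRE), Hotelling ellipse score diagnostics,
    aggregation of raw survey answers into an explanatory variable schema
    (including a landscape heterogeneity index and region-median
    standardization), a nineteen-model subset suite with resampling
    summaries, and a latent-factor synthetic farm data generator with
    exported ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
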