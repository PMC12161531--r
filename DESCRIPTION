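Package: epicyto
Title: Single-Cell Analysis of Histone-Modification Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell epigenomic profiling by mass cytometry
    (CyTOF) of histone modifications. Implements marker-matrix preprocessing
    (core-histone gating, arcsinh transform, variance-minimising core-histone
    normalization, batch-wise z-standardization), quantitative
    epigenetic-heterogeneity metrics on low-dimensional embeddings (convex-hull
    area, pairwise-distance quantiles, occupied-grid area, nearest-neighbour
    distances and their CDF ratios, Gini coefficients), three complementary
    reconstructions of the inter-modification influence network (gradient
    boosting with Shapley attributions, an ensemble Bayesian-network link
    probability, and partial correlations), a Markov-chain simulator of H3K27
    methylation/acetylation dynamics, and bimodal subpopulation analyses.
    A bundled synthetic-data generator with planted structure makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    RANN,
    uwot,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
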