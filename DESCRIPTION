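Package: netgain
Title: Baseline Brain Network Modularity as a Predictor of Cognitive Training Gains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating resting-state functional brain network organization
    to cognitive-training outcomes in small randomized cohorts. Builds Fisher-z
    connectivity matrices from ROI time series, binarizes them over a sweep of
    connection-density thresholds, and computes Newman modularity under a fixed
    community partition (e.g., the Power 264-ROI module assignments) or a
    deterministic leading-eigenvector spectral partition, along with the weighted
    within/between-module segregation statistic and its sign-handling variants.
    The statistical layer reproduces the machinery used in training studies:
    gain scores, Spearman and partial Pearson correlations with bias-corrected
    and accelerated (BCa) bootstrap confidence intervals, comparison of
    independent correlations via the Myers-Sirois rank-to-Pearson conversion and
    Fisher z, and 2x2 mixed ANOVA with partial eta-squared. A synthetic-cohort
    generator plants block-structured modular time series and copula-linked gain
    scores so that every pipeline stage is verifiable without access to the
    original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    boot,
    optparse
Config/testthat/edition: 3
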