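Package: GenomicOffset
Title: Genomic Offset Estimation from Latent-Factor Models and Gradient
    Forests Along Climate Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting climate-change maladaptation risk
    ("genomic offset") in natural populations. Implements latent-factor
    mixed-model genotype-environment association with genomic-inflation
    calibration and FDR candidate selection, the "genetic gap" offset (a
    quadratic form in the climate-change vector weighted by environmental
    effect sizes), and a gradient-forest offset built from per-locus
    regression forests whose split importances are aggregated into
    cumulative-importance turnover functions, with latent factors as
    confounding predictors. Includes bilinear raster extraction, ensemble
    means, train-time climate scaling, range-wide raster projection under
    emission scenarios, per-site aggregation with latitude regressions,
    and a synthetic-data generator emulating a paired elevation-site
    sampling design with structured genotypes and planted adaptive loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    geosphere,
    vcfR,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
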