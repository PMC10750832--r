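Package: wheatNRES
Title: Dynamic Phenotypic Analysis of Nitrogen Response in Wheat
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting nitrogen (N) responsiveness in winter
    wheat field trials from plot-level aerial phenotyping signals. The
    package extracts six canopy traits (plant height, canopy coverage,
    VARI, NDYI, a 3D canopy structure proxy, and GLCM angular second
    moment) from plot rasters, fits seasonal profile curves (Gaussian,
    Fourier, Weibull) to sparse flight-day observations, dissects the
    25-day post-fertilization response window into five-day compound
    growth rates (CGR), derives N efficiency comprehensive scores (NECS)
    and four-quadrant N-responsiveness classes from twelve yield and
    N-utilization indices, trains a weighted random-forest classifier
    (RF-NRES) on CGR features, and performs single-marker GLM association
    scans with population-structure covariates contrasting static and
    dynamic phenotypes. A seeded synthetic-trial generator reproduces the
    statistical structure of a 54-variety, three-treatment field design
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    minpack.lm,
    ranger,
    e1071,
    rpart,
    xgboost,
    class,
    mclust,
    jsonlite,
    yaml,
    png,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Phenotyping, Classification, GenomeWideAssociation, Regression
RoxygenNote: 7.3.3
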