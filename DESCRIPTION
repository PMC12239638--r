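Package: morphoquant
Title: Landmark Morphometrics and Quantitative Genetics of Life-History Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking biallelic life-history loci
    (vgll3, six6) to morphological traits in juvenile Atlantic salmon reared
    in a factorial common-garden design. Provides landmark input/output (TPS
    and wide CSV), quality filters with an audit trail, thin-plate-spline
    imputation of missing landmarks, generalized Procrustes analysis,
    extraction of 21 linear and centroid-size traits, multivariate shape
    models with residual-randomization permutation tests (Pillai's trace),
    pedigree-based mixed ("animal") models fitted by ML/REML on sparse
    Henderson mixed-model equations, Satterthwaite type-III tests, and
    variance decomposition into per-locus additive contributions,
    heritability, evolvability and repeatability with simulation-based
    confidence intervals. A synthetic-data generator reproduces the study's
    factorial breeding design with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    vegan,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
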