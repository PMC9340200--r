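Package: prstrat
Title: Population Structure Correction Strategies for Polygenic Score Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the choice of principal-component correction
    (cohort-specific versus projection onto external reference panels, applied
    in GWAS discovery and/or in polygenic-score validation) affects polygenic
    score performance and residual population-structure confounding. Provides a
    Balding-Nichols cohort simulator with structured and non-structured
    quantitative traits, variant quality control and LD pruning, principal
    component spaces with iterative outlier removal and least-squares sample
    projection, per-variant additive GWAS with genomic-inflation reporting,
    LD clumping with p-value thresholding for score construction, BIC-based
    validation-model grids, and residual-regression variance decomposition of
    trait, score, and principal components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
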