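Package: joint2strat
Title: Stratified and Marginal Genetic Effects from Joint
    Gene-Environment Interaction Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-variant genetic effect estimates, standard errors,
    sample sizes and Wald test statistics in the unexposed stratum, the
    exposed stratum and the marginal (no-interaction) model from summary
    statistics of a joint SNP plus SNP-by-exposure interaction model, as
    produced by meta-analysis of genome-wide gene-environment interaction
    screens. Includes a relative sample-size filter for variants with high
    genotype missingness, gzip-transparent readers for METAL-style
    interaction output, and a simulation framework that validates the
    estimators against individual-level regression fits (intraclass
    correlation agreement, type-I error calibration) and characterises
    bias from genotype-exposure correlation, misspecified exposure
    proportion and exposure-dependent phenotypic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
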