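Package: epimr
Title: Epigenetic Mendelian Randomization from Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for assessing putative downstream
    consequences of DNA methylation variation using genome-wide summary
    statistics. Selects conditionally independent cis-acting methylation
    quantitative trait loci (mQTL) as instruments via an approximate
    conditional-and-joint stepwise procedure, estimates causal effects of
    methylation on complex traits by two-sample Mendelian randomization
    (Wald ratio and inverse-variance weighting), assesses whether
    methylation, nearby gene expression and the trait share a single causal
    variant by three-trait Bayesian colocalization with approximate Bayes
    factors, and orients directions of effect with Steiger directionality
    tests, reverse MR and sign chaining against epigenome-wide association
    estimates. Includes a linkage-disequilibrium-structured simulator of
    coupled methylation, expression and trait summary statistics so the
    whole pipeline is testable without access to individual-level cohort
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    mvtnorm,
    utils,
    graphics,
    grDevices,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
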