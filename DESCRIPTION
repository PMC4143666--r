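Package: kinlong
Title: Kinship-Structured Association Testing for Longitudinal Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based genetic association analysis for quantitative traits
    measured repeatedly over time. Implements four kinship-structured linear
    mixed-model strategies (baseline-only, longitudinal mixed-effects, mean
    trait over visits, and two-stage regression of person-level BLUPs on SNP
    dosage), recursive pedigree kinship computation with gene-dropping
    validation, medication-aware blood-pressure preprocessing, and a
    simulation framework for power and type-I-error evaluation with genomic
    control, LD pruning and Bonferroni multiple-testing machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
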