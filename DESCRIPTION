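Package: equiburden
Title: Predicted Genetic Burden and Known-Variant Frequencies in Multi-Breed Horse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the predicted genetic burden of a multi-breed diploid
    cohort from a whole-genome VCF annotated by two variant-effect predictors
    (SnpEff-style ANN and VEP-style CSQ fields). Implements the dual-annotator
    consensus rule for deleterious variants, loss-of-function classification,
    per-sample and per-gene burden statistics, depth-of-coverage-adjusted
    estimated marginal means per breed, correlation of burden with published
    effective population sizes, and frequency reporting for catalogs of known
    phenotype-associated variants. Includes a seeded synthetic-cohort
    generator with recorded truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
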