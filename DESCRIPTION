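Package: phescore
Title: Phenotype Risk Scores for Mendelian Disease from Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes phenotype risk scores (PheRS) that quantify how much a
    person's diagnosis-code history resembles the clinical pattern of a given
    Mendelian disease. Maps ICD-9/ICD-10 occurrences to phecodes, assigns
    inverse-log-prevalence weights, aggregates weighted phecode indicators
    into per-person per-disease scores, residualizes scores against
    demographic covariates, validates scores with case/control comparisons
    based on diagnostic billing codes, and tests score-genotype associations
    under additive, dominant, recessive, and genotypic models. Includes a
    synthetic-cohort simulator with planted disease signal so the full
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14.0),
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
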