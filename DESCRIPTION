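Package: famlipid
Title: Family-Based Analysis of Dyslipidemia and Lipid Trait Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based analysis of dyslipidemia and serum lipid
    traits in longitudinal cohorts: pedigree parsing, kinship and numerator
    relationship matrices, typed relative-pair enumeration, ATP III lipid
    flagging and longitudinal dyslipidemia classification, point and periodic
    prevalence, family-history odds ratios, intraclass correlations by
    relative-pair type, and family-based heritability via profile-likelihood
    and Gibbs-sampling (Gaussian and probit liability) polygenic mixed models.
    Includes a pedigree and longitudinal-phenotype simulator with known
    variance components for validation, and a staged pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    Matrix,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
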