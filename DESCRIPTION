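Package: atmburden
Title: Rare-Variant Burden Analysis of Germline ATM Variants Against
    Population Reference Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-cohort rare-variant burden analysis of germline
    ATM variants against summary allele counts from a reference population
    (gnomAD-NFE-style AC/AN/homozygote tables). Implements consequence-based
    loss-of-function classification with curated overrides, allele-frequency
    and homozygote filters for missense variants of uncertain significance,
    exact two-by-two allele-count inference (point-probability Fisher p,
    sample and conditional maximum-likelihood odds ratios, conditional-exact
    and Wald confidence intervals), functional-domain annotation of the ATM
    protein, grouped and per-variant burden tests with genetically enriched
    subsets, internal case-control comparisons, familial cosegregation
    scoring, lollipop-plot export tables, and a synthetic cohort generator
    for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
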