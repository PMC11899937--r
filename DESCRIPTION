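Package: ldlprs
Title: Weighted SNP Scores for LDL Cholesterol with APOE Diplotype Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes a seven-SNP weighted polygenic score for LDL
    cholesterol in which five loci contribute additive risk-allele dosage
    terms and the APOE locus contributes a single epsilon-diplotype weight
    called from rs429358 and rs7412. Ships the score's weight tables,
    reads genotypes from VCF or wide TSV, simulates seeded case-control
    cohorts under Hardy-Weinberg proportions with configurable allele
    frequencies and a logistic disease model, and provides the matching
    statistical stage: tie-corrected rank tests, contingency-table tests
    without continuity correction, exact Fisher tests, and logistic
    regression with Wald odds-ratio intervals and backward selection.
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
    tidyr,
    tidyselect,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
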