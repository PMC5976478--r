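Package: lumdriver
Title: Somatic SNV Driver Prioritization for Luminal Breast Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic single nucleotide variants (SNVs) in
    small tumor exome cohorts, built around early-onset luminal (HER2-negative)
    breast cancer. Implements an evidence-based driver-candidate scoring rubric
    with CGC/PD/pd/Neutral classification, 96-context trinucleotide
    mutational-spectrum profiling, mutation load and rate statistics,
    cross-sample recurrence collapse, an exact Poisson-binomial
    background-mutation-rate significance test with Benjamini-Hochberg FDR, and
    cohort-level cross-tabulations of DNA-repair pathway and
    transcription-regulation genes. Ships reference evidence tables and gene
    sets as plain-text fixtures plus a seeded synthetic-cohort generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
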