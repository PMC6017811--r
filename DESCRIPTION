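Package: famspace
Title: Sequence-Space Analysis of AAA+ Protein Families with Companion
    Biochemical and Proteomic Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating protein families within a
    multiple sequence alignment by rank-encoded principal component analysis,
    classifying alignment positions as conserved or variable from component
    loadings, and computing sequence-logo information content. Companion
    modules cover gene presence/absence co-occurrence testing, Hill-equation
    fitting of binding curves, coupled-assay ATPase turnover, size-exclusion
    assembly fractions, and label-free quantification (LFQ) differential
    proteomics with volcano classification and COG class summaries. Seeded
    synthetic-data generators reproduce the statistical structure each stage
    assumes, so every analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
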