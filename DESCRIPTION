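Package: hetexpr
Title: Hybrid Expression Patterns, Allele-Specific Expression and
    Heterosis Indices for Parent-Hybrid Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptome-based heterosis analysis in
    parent-hybrid triads (two inbred parents and their F1), motivated by
    maize ear development but applicable to any diploid hybrid design.
    Computes FPKM from read-count tables, calls differentially expressed
    genes with exact tests on pooled counts, classifies each gene's hybrid
    expression pattern against the mid-parent value (additive,
    over-dominant, under-dominant, parent-dominant, conserved), calls
    allele-specific expression from SNP-level allelic read counts with
    exact binomial tests and gene-level aggregation, computes trait-level
    heterosis indices (over-standard heterosis, degree of dominance d/a),
    and runs annotation-driven over-representation tests. A seeded
    negative-binomial simulator generates triad count matrices, SNP allele
    counts and trait tables with exported ground truth so every stage can
    be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
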