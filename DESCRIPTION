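Package: rrnaprimer
Title: rRNA Read Mining and SSU Primer Coverage Evaluation for Shotgun
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines small- and large-subunit rRNA reads out of shotgun
    metagenome and metatranscriptome datasets and evaluates degenerate SSU
    PCR primers against them. Reads are oriented and accepted by a k-mer
    search score against a gapped reference alignment, classified with a
    k-mer naive-Bayes bootstrap classifier, and projected into the
    reference column space by template-based (NAST-style) alignment. A
    co-aligned full-length anchor sequence fixes each primer's column
    interval; binding sites are extracted with flanking pad bases,
    re-aligned to every non-degenerate primer variant, and typed per
    position (match, substitution, insertion, deletion, missing). Outputs
    include per-read match-type tables and per-primer summary statistics,
    among them taxon-level coverage. A deterministic mock-community
    simulator (genomes with embedded rRNA operons, fixed read length,
    fold coverage, exact or uniform-substitution error models) makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
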