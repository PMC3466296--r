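Package: malines
Title: Mutation Rate Estimation from Mutation Accumulation Line Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome sequencing of haploid
    mutation accumulation (MA) lines: decodes per-site read pileups into
    base counts, builds a self-mapping uniqueness mask for short-read
    mappability, classifies every site per line as a unique point
    mutation, an unchanged (reference-confirming) site, or excluded under
    symmetric focal/confirmation filtering rules, calls heteroplasmic
    mitochondrial mutations with frequency-weighted rate estimation and
    two cutoff-selection procedures, and reports per-site per-generation
    mutation rates with exact (Garwood) Poisson confidence intervals.
    Includes a synthetic-data generator with planted mutations, shared
    ancestral differences, heteroplasmies, and per-read errors so that
    every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
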