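Package: biasassay
Title: Coverage and Error Bias Assays for Shotgun Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assays for characterizing and measuring coverage bias and
    error bias in whole-genome shotgun sequencing alignments. Computes
    per-base relative coverage, bias-motif scans and motif relative
    coverage, GC-bias curves, undercoverage tables, CIGAR-level
    mismatch/insertion/deletion attribution and error-rate profiles (by
    GC content and homopolymer length), coverage-depression scoring of
    transcription start sites ("bad promoters"), depth normalization and
    technology-mixing experiments, and a filter cascade for discovering
    undercovered regions not explained by known bias motifs. Includes a
    synthetic-data generator that produces references and aligned reads
    with controllable GC-dependent coverage bias and context-dependent
    error rates, together with a ground-truth event log.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
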