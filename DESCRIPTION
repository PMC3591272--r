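Package: threeprime
Title: Analysis of Yeast 3' End Reporter Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the effect of 3' end (terminator/3'UTR)
    sequences on gene expression in reporter libraries. Covers plate-reader
    growth-curve processing into per-cell protein production rates,
    polyadenylation-site mapping from 3'RACE reads against a small cloned
    reference, polyA-anchored sequence-feature scans (A/T content windows,
    k-mers, processing motifs, pairing-score proxy for secondary structure),
    nested-regression variance partitioning, and transcriptional burst
    size/frequency extraction from single-cell fluorescence. Includes a
    synthetic-data generator that emulates every input class with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
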