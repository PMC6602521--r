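Package: cistromeGO
Title: Functional Enrichment Analysis of Transcription Factor ChIP-Seq Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks genes by a transcription factor's regulatory potential
    computed from ChIP-seq peaks, with weights decaying exponentially in
    peak-to-TSS distance, and performs threshold-free GO/KEGG enrichment on
    the resulting gene ranking using an exact minimum-hypergeometric (mHG)
    test. Supports a solo mode (peaks only) and an ensemble mode that
    integrates a differential-expression table by rank product, classifies
    cistromes as promoter- or enhancer-dominant to choose the decay
    distance, adjusts regulatory potential against a baseline over
    reference cistromes, and ships a seeded synthetic-fixture generator
    for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
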