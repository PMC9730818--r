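Package: breakmark
Title: Epigenomic Context of Spontaneous and Replication-Stress-Induced DNA Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit associating DNA double-strand break (DSB) interval
    sets with chromatin features. Implements a per-chromosome interval-shuffle
    permutation test for overlap enrichment, feature-centered binned aggregation
    profiles, condition set algebra (shared/unique DSBs), gene-size-stratified
    hit densities, radial-position (GP-seq) scoring of DSB regions against the
    genomic background, and matched-null random-forest classification of DSBs
    from feature signals or feature distances. Ships a synthetic-genome
    generator with planted structure so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    randomForest,
    pROC,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
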