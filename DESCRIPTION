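Package: auxphase
Title: Auxin-Response Profiling Across Plant Generations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of transcriptional auxin responses in the
    two generations (gametophyte and sporophyte) of land plants. Extracts
    TSS-anchored promoter windows from a genome and GFF3 annotation, scans
    them for TGTCNN auxin-response elements and their spaced repeats (direct,
    inverted and everted orientations, spacers 0-25 bp), and tests gene-level
    enrichment with Fisher's exact test. Summarises differential-expression
    tables (activation:repression dominance, fold-change amplitude, top-k
    decomposition with exact rank-sum tests), quantifies cross-species
    overlap of responsive gene sets in orthogroup space, computes leaf vein
    network indices with an F-then-t two-stage comparison, and quantifies
    nuclear fluorescence intensities for ploidy inference. A seeded
    synthetic-data generator with truth tables makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
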