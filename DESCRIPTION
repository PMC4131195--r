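Package: tmrnakit
Title: Reconciliation and Characterization of tmRNA, tRNA and smpB Gene
    Annotations in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding, reconciling and characterizing the
    trans-translation machinery (the tmRNA gene ssrA, its protein partner
    gene smpB, and the tRNA set) in bacterial genome annotations.
    Merges and resolves overlapping calls from multiple gene predictors,
    classifies tRNA calls as valid or questionable, refines tmRNA termini
    against a terminus-motif database, calibrates profile-score thresholds
    against decoy hits, evaluates raw predictor output by sequential
    overlap with ordered reference gene sets, classifies CDS x RNA-gene
    overlaps and flags candidate non-stop mRNAs, clusters smpB gene
    neighborhoods, and runs sequence-level diagnostics (acceptor-stem
    pairing, tag reading-frame conservation, ORF integrity, alignment
    region presence). Includes a deterministic synthetic-data generator
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
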