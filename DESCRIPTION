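Package: duplexmir
Title: Reference-Free Discovery of Mature miRNA Duplexes from Small RNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers mature microRNA duplexes directly from small RNA
    sequencing reads without a reference genome or precursor sequences.
    Reads are collapsed to unique tags, merged into contigs by exact
    terminal suffix-prefix overlaps, paired into candidate duplexes by
    global complementarity alignment with affine gaps, G:U wobble pairing
    and free 3' overhangs, and encoded as pairing-state patterns over
    {M, X, I, D}. Patterns are scored against length-clustered long-range
    transition-probability profiles and classified with a MultiBoost
    ensemble of best-first decision trees. Includes iso-miR grouping,
    read-count expression values, a seeded synthetic duplex/read simulator
    for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    BiocGenerics,
    tools,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
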