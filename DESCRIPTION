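Package: circjunction
Title: De Novo Circular RNA Detection from Clipped RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects circular RNAs (circRNAs) de novo from paired-end RNA-seq
    alignments produced by a split-read-capable aligner. Soft- and hard-clipped
    alignment records are classified into left- and right-junction clusters by
    their CIGAR shape, filtered by paired-end mapping (PEM) signals, and joined
    into back-spliced junction (BSJ) read pairs whenever the two reads share a
    local similar sequence that spans the circular junction, found by
    Smith-Waterman local alignment. Junctions are clustered with a positional
    tolerance and filtered by read support and mapping quality. The package
    also ships a paired-end read simulator for circular and linear transcripts
    (including small circles and short flanking exons), a simplified split
    aligner emitting SAM, and evaluation utilities (sensitivity, precision,
    F1, and an RNase R enrichment criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    Rsamtools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
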