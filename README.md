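# circjunction

De novo detection of circular RNAs (circRNAs) from paired-end RNA-seq
alignments, for transcriptomics researchers who want sensitive,
annotation-free circRNA calls from the SAM/BAM output of any
split-read-capable aligner.

## The method

Back-splicing joins a downstream 5' splice donor at genomic position
*d* to an upstream 3' splice acceptor at position *a*, so a read
spanning the back-spliced junction (BSJ) aligns to the linear reference
as two segments in reversed genomic order. The aligner reports these as
clipped records — `xS yM` at the acceptor, `xM yS` at the donor — but
drops the short side of an unbalanced split, which starves methods that
need reciprocal clipped records per read.

`circjunction` instead decides junction support at the level of read
*pairs*: any two BSJ reads of one junction must share a **local similar
sequence** that covers both sides of the junction in both reads. The
pipeline is

1. classify clipped records into left-junction (acceptor-side) and
   right-junction (donor-side) clusters by CIGAR shape;
2. filter by paired-end mapping (PEM) signals — the mate of a junction
   read must map inside the inferred circle `[a, d]` with FR-consistent
   orientation — and enumerate candidate left x right pairs on the same
   chromosome within a maximum span;
3. accept a pair iff Smith–Waterman local alignment of the two read
   sequences yields >= 15 columns, with at most `ceiling(0.02 x read
   length)` mismatched and gapped columns, spanning both reads' clip
   boundaries;
4. cluster junctions within a 5-base tolerance (single linkage, modal
   representative) and keep candidates with >= 2 distinct supporting
   reads per splice site and mean mapping quality >= 10.

Predictions are scored against a truth set by sensitivity
`TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic mean F1; an
RNase R enrichment criterion (treated BSJ count >= 3 x untreated,
among candidates with untreated count >= 4) labels real-data candidates
TP/FP and yields an FDR.

The package also ships a deterministic simulator (`simulate_dataset`):
synthetic genome + gene models, circRNA truth sets across five subtypes
(multi-exon, single-exon, intron-retained, smaller-than-read, short
flanking exon), paired FASTQ with substitution errors, and a simplified
split-aligner SAM emitter that reproduces the unbalanced-split
pathology.

## Worked example

Simulate a 200 kb genome with 20 genes and 10 circRNAs at 10x circular /
10x linear depth, detect, and score:

```r
library(circjunction)

cfg <- sim_config(genome_length = 200000L, n_genes = 20L, n_circ = 10L,
                  seed = 7L)
sim  <- simulate_dataset(cfg, "example_out")
cand <- detect_circRNAs(sim$paths$sam, verbose = TRUE)
#> alignment records: 4053
#> left-junction cluster: 926; right-junction cluster: 901
#> candidate pairs after PEM filter: 96468
#> accepted BSJ read pairs: 107
#> junction clusters: 10
#> candidates after final filters: 10

cand[, .(circ_id, bsj_count, n_left, n_right, mean_mapq)]
#>                  circ_id bsj_count n_left n_right mean_mapq
#>  1:   synth1:31769|32754         7      1       6        60
#>  2:   synth1:54845|56077         4      1       3        60
#>  3: synth1:126431|126737         4      1       3        60
#>  ...
#> 10: synth1:197474|198767         9      6       3        60

match_predictions(cand, sim$truth, boundary_tol = 0)
#> TP=10 FP=0 FN=0  sensitivity=1.0000 precision=1.0000 F1=1.0000

write_candidates(cand, "circRNAs.tsv", bed = "circRNAs.bed")
```

Each candidate row is one junction cluster: `circ_id` encodes
`chrom:acceptor|donor` (1-based inclusive), `bsj_count` is the number of
distinct BSJ read names supporting it (every accepted read spans both
splice sites), and `n_left`/`n_right` count reads anchored on each side.
Here all ten preset circles — including one 57-base circle shorter than
the reads and one with a short flanking exon — are recovered exactly,
with no false calls. A command-line front end with the same options
lives in `inst/cli/circjunction.R` (subcommands `detect`, `simulate`,
`evaluate`, `rnase-r`).

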