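---
title: "Detecting circular RNAs from clipped alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular RNAs from clipped alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circjunction)
```

## The detection problem

Back-splicing covalently joins a downstream 5' splice donor to an upstream
3' splice acceptor, yielding a circular RNA. In RNA-seq data the only
direct evidence for a circle is the back-spliced junction (BSJ) read: a
read whose 5' part comes from the end of the circle (near the donor) and
whose 3' part wraps around to its start (the acceptor). Against a linear
reference such a read aligns as two segments in *reversed* genomic order,
which split-read aligners report as clipped records: a record at the
acceptor clipped at its 5' end (`xS yM`) and/or a record at the donor
clipped at its 3' end (`xM yS`).

Aligners only report both records when both segments are long enough to
anchor. BSJ reads with an unbalanced split — a short segment on one side
of the junction — typically yield a single clipped record, and methods
that require reciprocal clipped pairs per read (paired chiastic clipping)
lose them. The idea implemented here recovers those reads at the level of
read *pairs*: any two BSJ reads of the same junction must share a local
similar sequence that covers both sides of the junction, whether or not
either read was split by the aligner. Optimal local alignment between the
two read sequences decides this directly, independent of read length.

## Pipeline

1. **Extraction and classification** (`extract_clipped_reads`). Every
   alignment record with a clip of at least `min_clip` bases enters the
   left-junction cluster (`xS|H yM`, candidate acceptor side), the
   right-junction cluster (`xM yS|H`, candidate donor side), or both for
   three-segment records (`xS yM zS`), which arise when a circle or its
   flanking exon is shorter than the read. Secondary and supplementary
   records are kept — split alignments carry the signal — while
   duplicates and QC failures are dropped. Hard-clipped records get their
   full sequence back from the read's primary record (reverse-complemented
   across strands); irrecoverable ones are dropped and counted.
2. **PEM filtering and pair enumeration** (`enumerate_pairs`). The two
   segments of a genuine BSJ read delimit the circle, so the read's mate
   must fall inside the inferred interval `[acceptor, donor]`
   (boundaries inclusive; the leftmost mapped position is used for
   clipped mates). In an FR library the acceptor-side read must be `+`
   with a `-` mate and the donor-side read `-` with a `+` mate; pairs
   with equal directions are rejected, and `--library-layout rf` swaps
   the expectations. Candidate pairs additionally require the same
   chromosome, the left read upstream of the right, a span of at most
   `max_span`, and mapping quality `min_mapq_pair` for both members.
3. **Local-similarity identification** (`accept_pair`). Smith–Waterman
   local alignment of the two read sequences must produce an alignment of
   at least `min_overlap` columns with at most `max_mismatch` mismatching
   and `max_gap` gapped columns that covers both reads' clip boundaries
   (`spans_junction`). Pairs passing this are putative BSJ read pairs.
4. **Clustering and final filters** (`cluster_junctions`,
   `apply_final_filters`). Junctions within `tolerance` bases on both
   boundaries merge by single linkage; the representative is the modal
   member junction (ties to the smallest coordinates) so reported
   junctions stay on observed loci. Candidates then need at least
   `min_side_support` distinct supporting reads per splice site and a
   mean supporting-record mapping quality of `min_mean_mapq`.

### Counting support per splice site

Every read of an accepted pair carries a similar region that spans the
junction, i.e. bases on both sides of both splice sites; each distinct
read name therefore supports the acceptor and the donor alike, and
`support_left = support_right = bsj_count`. The alternative — crediting a
read only to the side its matched segment lies on — would demand at least
two `+`-strand acceptor-side reads *and* two `-`-strand donor-side reads
per junction. At low circular depth (3–10x) the expected number of usable
BSJ reads per strand is near one, so that rule suppresses exactly the
low-expression circles this method is designed to keep. Per-side member
counts are still reported (`n_left`, `n_right`) for diagnostics.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_clip` | 10 bases | shortest clip treated as junction evidence; shorter clips are dominated by sequencing error |
| `min_mapq` | 1 | ingestion floor; excludes pure multi-placement records (MAPQ 0) |
| `max_span` | 200 kb | largest circle span considered; covers known exonic circRNA spans without admitting chromosome-scale artifacts |
| `min_mapq_pair` | 10 | "reasonable mapping score" for both pair members |
| scoring | +1 / −1 / −2 / −1 | match, mismatch, gap open, gap extend; standard nucleotide local-alignment weights |
| `max_mismatch`, `max_gap` | `ceiling(0.02 × read length)` | similar-region cleanliness, scaled so the expected error load of longer overlaps does not starve detection |
| `min_overlap` | 15 bases | shortest similar region; a chance 15-mer match has probability ~4^-15 per offset |
| `tolerance` | 5 bases | junction clustering radius; absorbs micro-homology shifts without merging distinct circles |
| `min_side_support` | 2 reads | distinct read names required per splice site |
| `min_mean_mapq` | 10 | reliable-mapping filter on the cluster |

## Numerical and algorithmic choices

* **Gap model.** The first column of a gap run costs `gap_open`, each
  further column `gap_extend`. (Equivalent to Biostrings'
  `gapOpening = |gap_open| − |gap_extend|`, `gapExtension = |gap_extend|`,
  which the test suite uses as an independent cross-check.)
* **Traceback determinism.** The reported optimum is the first maximal
  cell in row-major order; within a cell, diagonal beats vertical beats
  horizontal, and gap-open beats gap-extend. Equal-scoring optima
  therefore resolve identically on every run and partition count.
* **"Dashes".** Gap *columns* are counted against `max_gap`, not gap
  runs; with the default limits the distinction is immaterial for
  substitution-dominated data.
* **Batch screening.** Enumerated pairs can reach millions on deep
  libraries because the PEM constraint is loose for wide spans. Before
  the full dynamic program, each pair is screened by ungapped comparison
  at the clip-consistent diagonal offsets (the offset implied by the two
  clip boundaries, ± `max_gap`); a pair whose best diagonal still shows
  more than `max_mismatch + max_gap` mismatches cannot satisfy the
  thresholds for substitution-only data and is rejected without the DP.
  Survivors get the full Smith–Waterman decision, so on indel-free data
  the batch path is exactly `accept_pair` applied per pair (asserted in
  the tests). Data with real indels near a junction could in principle be
  rejected by the screen where an exhaustive DP would accept; the screen
  is a documented speed/completeness trade-off.
* **Coordinates.** SAM 1-based inclusive throughout; only the BED writer
  converts to 0-based half-open. Clip sides are defined in reference
  orientation as stored in SAM; strand is carried separately, and
  sequences are compared in reference orientation.
* **Degenerate inputs.** Empty clusters, empty pair sets and empty
  candidate tables flow through and produce header-only outputs; a
  zero-score alignment never spans a junction; undefined evaluation
  ratios are reported as 0 with a warning.

## The simulator's generative model

`simulate_dataset` emulates, at desk scale, a read simulator for
non-canonical transcripts plus a split aligner:

* an i.i.d. uniform ACGT genome (default 500 kb) with non-overlapping
  plus-strand genes (default 50; 4–8 exons of 30–400 bases, introns of
  100–1000 bases — exon lengths bracket the human median of ~140 bases);
* a truth set of circles (default 30) over five subtypes: multi-exon,
  single-exon, intron-retained, *small* (shorter than the read) and
  *short flanking exon* (first exon shorter than the read), with
  junctions always on exon edges;
* paired-end reads at configurable depth, read length, insert size
  (normal, default 300 ± 30) and per-base substitution error rate
  (default 1%); circular transcripts are sampled with modular
  coordinates, so BSJ reads and wrap-around reads of small circles arise
  naturally, and `round(depth × L / (2 × read_len))` fragments per
  transcript give the nominal fold coverage;
* an alignment emitter that anchors each read on its longest genomic
  segment and emits supplementary clipped records only for other
  segments of at least `split_min = 19` bases (mirroring aligner minimum
  seed lengths). This deliberately reproduces the unbalanced-split
  pathology: the short side of an unbalanced BSJ read is dropped, so the
  local-similarity rescue is genuinely exercised. One RNG stream is
  seeded from `config$seed` and consumed in a fixed order (genome, gene
  models, circles, reads, errors), making every artefact byte-identical
  across runs.

What the simulator does **not** emulate — and what passing tests on it
therefore cannot show about real data:

* repeats, paralogy and mapping ambiguity: every record is uniquely
  placed (MAPQ 60), so the false positives that dominate real precision
  (repeat-driven mismapping on a real genome) cannot occur, and nothing
  caps sensitivity at saturating depth;
* insertion/deletion sequencing errors and quality-dependent error
  models;
* junction micro-homology handling by a real aligner, which extends
  matches across the junction and shifts reported boundaries; the
  emitter splits exactly at the junction, so simulation scoring can use
  a boundary tolerance of 0;
* annotation-free transcript diversity (alternative splicing, intergenic
  transcription, rolling-circle concatemers beyond simple wraps).

A further finite-sampling caveat: recovery of a circle requires at least
one `+`-strand acceptor-side read and one `-`-strand donor-side read
whose flanks reach `min_clip`. At exactly 10x circular depth the
expected count per strand is ~3 and a few percent of circles draw none;
the noiseless-recovery property is therefore exercised at 30x, where the
probability of such a gap is negligible and any miss would indicate a
pipeline defect rather than sampling.

## Problem sizes used by the checks

The test suite and the acceptance script run the simulation benchmarks on
the 500 kb / 50-gene / 30-circle configuration with simulator defaults:
the depth sweep (3, 10, 20, 50x circular over 10x linear at 100 bases),
the read-length condition (10x circular, 70x linear, 100 bases) and the
linear-depth sweep at 50 bases (10–70x linear). The acceptance script
averages three consecutive seeds per condition; the test suite uses one
seed per condition, and smaller genomes (60–300 kb) for unit and
property tests. Each condition completes in well under five minutes on
one CPU.

## Known limitations

* Precision on the synthetic genome is near 1 and sensitivity saturates
  at high depth, for the generative-model reasons above; both are
  optimistic relative to real alignments.
* The per-pair decision uses the *optimal* alignment's statistics; a
  sub-optimal shorter alignment that would pass the thresholds does not
  rescue a pair whose optimum is too dirty.
* Greedy nearest matching in evaluation can differ from optimal
  assignment when truths overlap within the tolerance; with exact
  simulated truth this does not arise.
* No GT–AG splice-motif filter is applied: detection stays
  annotation-free and motif-free by design.
* BSJ read counts are the only abundance measure; internal circle
  structure is not reconstructed.
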