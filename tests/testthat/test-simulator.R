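small_cfg <- function(...) {
  sim_config(genome_length = 80000L, n_genes = 8L, n_circ = 5L, seed = 21L,
             ...)
}

test_that("the generator is byte-deterministic under a seed", {
  d1 <- simulate_dataset(small_cfg(), tempfile("det1"))
  d2 <- simulate_dataset(small_cfg(), tempfile("det2"))
  for (f in c("genome", "fastq1", "fastq2", "truth", "sam", "gtf")) {
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]),
                     info = f)
  }
})

test_that("gene models respect the configured ranges and never overlap", {
  gen <- generate_genome(sim_config(genome_length = 200000L, n_genes = 15L,
                                    exon_length_range = c(100L, 500L),
                                    seed = 2L))
  elen <- gen$genes$end - gen$genes$start + 1L
  expect_true(all(elen >= 100L & elen <= 500L))
  spans <- gen$genes[, .(lo = min(start), hi = max(end)), by = gene_id]
  data.table::setorder(spans, lo)
  expect_true(all(spans$lo[-1] > spans$hi[-nrow(spans)]))
  expect_lte(max(spans$hi), 200000L)
  ## zero genes: genome with empty annotation
  empty <- generate_genome(sim_config(genome_length = 10000L, n_genes = 0L))
  expect_identical(nrow(empty$genes), 0L)
  expect_identical(nchar(empty$seq), 10000L)
})

test_that("circRNA subtypes obey their defining constraints", {
  cfg <- sim_config(genome_length = 400000L, n_genes = 30L, n_circ = 20L,
                    seed = 13L)
  gen <- generate_genome(cfg)
  truth <- sample_circRNAs(gen$genes, cfg)
  expect_identical(nrow(truth), 20L)
  ## exact proportions by largest-remainder construction
  expect_identical(as.integer(table(truth$subtype)[c(
    "multi_exon", "single_exon", "intron_retained", "small",
    "short_flank")]), c(10L, 4L, 2L, 2L, 2L))
  expect_true(all(truth[subtype == "small", circ_length] < cfg$read_len))
  for (i in which(truth$subtype == "short_flank")) {
    seg <- truth$segments[[i]]
    expect_lt(seg$end[1] - seg$start[1] + 1L, cfg$read_len)
    expect_gt(nrow(seg), 1L)
  }
  for (i in which(truth$subtype == "intron_retained")) {
    seg <- truth$segments[[i]]
    expect_identical(nrow(seg), 1L) # contiguous genomic span incl. intron
  }
  ## every junction boundary falls on exon edges of the source models
  expect_true(all(truth$start %in% gen$genes$start))
  expect_true(all(truth$end %in% gen$genes$end))
  ## circ_length is the sum of constituent segments
  for (i in seq_len(nrow(truth))) {
    seg <- truth$segments[[i]]
    expect_identical(truth$circ_length[i],
                     sum(seg$end - seg$start + 1L))
  }
  ## a subtype that cannot be placed errors after bounded retries
  cfg_bad <- sim_config(genome_length = 100000L, n_genes = 4L,
                        exon_length_range = c(200L, 300L),
                        subtype_mix = c(multi_exon = 0, single_exon = 0,
                                        intron_retained = 0, small = 1,
                                        short_flank = 0),
                        n_circ = 2L, read_len = 100L, seed = 1L)
  genb <- generate_genome(cfg_bad)
  expect_error(sample_circRNAs(genb$genes, cfg_bad), "small")
})

test_that("read counts follow the coverage identity", {
  ## depth 10, 1000 bp transcript, 100 bp reads: 50 pairs
  genes <- data.table::data.table(gene_id = "g001", exon_rank = 1L,
                                  start = 1001L, end = 2000L)
  cfg <- sim_config(genome_length = 5000L, n_genes = 1L, n_circ = 0L,
                    depth_linear = 10, read_len = 100L, seed = 4L)
  set.seed(4)
  genome <- random_dna(5000L)
  reads <- simulate_reads(NULL, genes, genome, cfg)
  expect_identical(nrow(reads), 100L) # 50 pairs
})

test_that("error-free reads are exact substrings of the circularised transcript", {
  cfg <- small_cfg(error_rate = 0)
  gen <- generate_genome(cfg)
  truth <- sample_circRNAs(gen$genes, cfg)
  reads <- simulate_reads(truth, gen$genes, gen$seq, cfg)
  circ_reads <- reads[origin == "circ"]
  expect_gt(nrow(circ_reads), 0L)
  for (i in sample(nrow(circ_reads), min(50L, nrow(circ_reads)))) {
    r <- circ_reads[i]
    seg <- truth[circ_id == r$origin_id, segments][[1]]
    tx <- paste(substring(gen$seq, seg$start, seg$end), collapse = "")
    doubled <- strrep(tx, ceiling(cfg$read_len / nchar(tx)) + 1L)
    expect_true(grepl(r$seq, doubled, fixed = TRUE),
                info = r$qname)
  }
})

test_that("mean linear coverage tracks depth_linear within 10 percent", {
  cfg <- sim_config(genome_length = 150000L, n_genes = 10L, n_circ = 0L,
                    exon_length_range = c(200L, 400L),
                    depth_linear = 20, read_len = 100L, seed = 31L)
  gen <- generate_genome(cfg)
  reads <- simulate_reads(NULL, gen$genes, gen$seq, cfg)
  lens <- gen$genes[, .(L = sum(end - start + 1L)), by = gene_id]
  obs <- reads[, .(bases = .N * cfg$read_len), by = origin_id]
  cov <- merge(lens, obs, by.x = "gene_id", by.y = "origin_id")
  cov <- cov[L >= 10L * cfg$read_len]
  expect_gt(nrow(cov), 0L)
  expect_true(all(abs(cov$bases / cov$L - 20) / 20 < 0.10))
})

test_that("emitted SAM round-trips through Rsamtools and splits correctly", {
  sim <- simulate_dataset(small_cfg(), tempfile("rt"))
  ## parses as BAM with the declared reference
  bam <- Rsamtools::asBam(sim$paths$sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam)[[1]]
  expect_gt(length(res$qname), 0L)
  expect_identical(levels(res$rname), "synth1")
  expect_identical(length(readLines(sim$paths$sam)) - 3L,
                   length(res$qname))
  ## FASTQ round-trips through Biostrings
  fq <- Biostrings::readDNAStringSet(sim$paths$fastq1, format = "fastq")
  expect_identical(length(fq), sum(sim$reads$mate_index == 1L))
  expect_true(all(Biostrings::width(fq) == small_cfg()$read_len))
  ## genome FASTA round-trips
  fa <- Biostrings::readDNAStringSet(sim$paths$genome)
  expect_identical(as.character(fa[[1]]), sim$genome)
})

test_that("the emitter follows the split-record rules", {
  genes <- data.table::data.table(gene_id = "g001", exon_rank = 1L,
                                  start = 2001L, end = 4000L)
  cfg <- sim_config(genome_length = 10000L, n_genes = 1L, n_circ = 1L,
                    depth_linear = 0, depth_circ = 1, read_len = 100L,
                    error_rate = 0, seed = 6L)
  truth <- data.table::data.table(
    circ_id = "circA", chrom = "synth1", start = 2001L, end = 3000L,
    subtype = "single_exon", circ_length = 1000L,
    segments = list(data.table::data.table(start = 2001L, end = 3000L)))
  mk_reads <- function(tstarts) {
    data.table::data.table(
      qname = sprintf("q%02d", seq_along(tstarts)), mate_index = 1L,
      origin = "circ", origin_id = "circA", trans_idx = 1L,
      tstart = as.integer(tstarts), strand = "+",
      rlen = 100L, seq = strrep("A", 100L))
  }
  parse_sam <- function(path) {
    ln <- grep("^@", readLines(path), value = TRUE, invert = TRUE)
    do.call(rbind, strsplit(ln, "\t"))
  }
  sam <- tempfile(fileext = ".sam")

  ## BSJ read split 70/30: primary 70M30S at the donor side plus a
  ## supplementary 70S30M at the acceptor
  emit_alignments(mk_reads(931L), genes, truth, cfg, sam)
  m <- parse_sam(sam)
  expect_identical(sort(m[, 6]), sort(c("70M30S", "70S30M")))
  expect_identical(m[m[, 6] == "70M30S", 4], "2931")  # donor-side origin
  expect_identical(m[m[, 6] == "70S30M", 4], "2001")  # acceptor
  flags <- as.integer(m[, 2])
  expect_identical(sum(bitwAnd(flags, 2048L) > 0L), 1L)

  ## split 95/5: the 5-base segment is below split_min and is dropped
  emit_alignments(mk_reads(906L), genes, truth, cfg, sam)
  m2 <- parse_sam(sam)
  expect_identical(m2[, 6], "95M5S")

  ## a 100 bp read on an 80 bp circle: clips on both ends of the full
  ## circle record
  truth80 <- data.table::data.table(
    circ_id = "circA", chrom = "synth1", start = 2001L, end = 2080L,
    subtype = "small", circ_length = 80L,
    segments = list(data.table::data.table(start = 2001L, end = 2080L)))
  emit_alignments(mk_reads(71L), genes, truth80, cfg, sam)
  m3 <- parse_sam(sam)
  ## wrap pieces collapse onto the clipped-both-ends full-circle record
  expect_identical(m3[, 6], "10S80M10S")
  expect_identical(m3[, 4], "2001")
})
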