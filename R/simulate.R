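#' Simulation configuration
#'
#' Bundles every tunable of the synthetic data generator: a uniform-random
#' genome with non-overlapping multi-exon gene models, a set of circRNAs
#' drawn from those models across five subtypes, paired-end reads with
#' substitution errors from both circular and linear transcripts, and a
#' simplified split-aligner SAM emitter.
#'
#' @param genome_length Genome size in bases.
#' @param n_genes Number of non-overlapping genes.
#' @param exon_length_range,intron_length_range Inclusive base ranges that
#'   exon and intron lengths are drawn from (uniform).
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param n_circ Number of circRNAs in the truth set.
#' @param subtype_mix Named proportions over subtypes `multi_exon`,
#'   `single_exon`, `intron_retained`, `small` (circle shorter than the
#'   read), `short_flank` (a terminal exon shorter than the read).
#' @param depth_circ,depth_linear Fold read coverage of circular and
#'   linear transcripts.
#' @param read_len Read length in bases.
#' @param insert_mean,insert_sd Fragment-length distribution (normal).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; one RNG stream is consumed in documented
#'   order (genome, gene models, circles, reads, errors).
#' @param split_min Minimum genomic segment length (bases) for which the
#'   emitter reports a supplementary clipped record; shorter split
#'   segments are silently dropped, mirroring aligner seed limits.
#' @param seqname Reference sequence name used throughout.
#' @param min_gene_gap Minimum intergenic gap in bases.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 500000L, n_genes = 50L,
                       exon_length_range = c(30L, 400L),
                       intron_length_range = c(100L, 1000L),
                       exons_per_gene = c(4L, 8L), n_circ = 30L,
                       subtype_mix = c(multi_exon = 0.5, single_exon = 0.2,
                                       intron_retained = 0.1, small = 0.1,
                                       short_flank = 0.1),
                       depth_circ = 10, depth_linear = 10,
                       read_len = 100L, insert_mean = 300, insert_sd = 30,
                       error_rate = 0.01, seed = 1L, split_min = 19L,
                       seqname = "synth1", min_gene_gap = 200L) {
  stopifnot(genome_length > 0, n_genes >= 0, n_circ >= 0,
            length(exon_length_range) == 2,
            exon_length_range[1] >= 1,
            exon_length_range[1] <= exon_length_range[2],
            intron_length_range[1] >= 1,
            intron_length_range[1] <= intron_length_range[2],
            exons_per_gene[1] >= 1, exons_per_gene[1] <= exons_per_gene[2],
            depth_circ >= 0, depth_linear >= 0, read_len >= 20,
            insert_sd >= 0, error_rate >= 0, error_rate < 1)
  if (abs(sum(subtype_mix) - 1) > 1e-8) {
    stop("subtype_mix proportions must sum to 1")
  }
  structure(list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    exons_per_gene = as.integer(exons_per_gene), n_circ = as.integer(n_circ),
    subtype_mix = subtype_mix, depth_circ = depth_circ,
    depth_linear = depth_linear, read_len = as.integer(read_len),
    insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate, seed = as.integer(seed),
    split_min = as.integer(split_min), seqname = seqname,
    min_gene_gap = as.integer(min_gene_gap)), class = "sim_config")
}

#' Generate a synthetic genome with gene models
#'
#' Draws an i.i.d. uniform ACGT genome and places non-overlapping
#' plus-strand gene models whose exon and intron lengths come from the
#' configured ranges. Seeds the run's RNG stream from `config$seed`;
#' downstream simulator steps continue the same stream.
#'
#' @param config A [sim_config()].
#' @return A list with `seq` (genome as a single string), `seqname`, and
#'   `genes` (a `data.table` of exons: `gene_id`, `exon_rank`, `start`,
#'   `end`).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  seq <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                      replace = TRUE), collapse = "")
  if (config$n_genes == 0L) {
    return(list(seq = seq, seqname = config$seqname,
                genes = data.table(gene_id = character(0),
                                   exon_rank = integer(0),
                                   start = integer(0), end = integer(0))))
  }
  exr <- config$exon_length_range
  inr <- config$intron_length_range
  struct <- lapply(seq_len(config$n_genes), function(i) {
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    exons <- sample(exr[1]:exr[2], n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(inr[1]:inr[2], n_ex - 1L,
                                     replace = TRUE) else integer(0)
    list(exons = exons, introns = introns,
         len = sum(exons) + sum(introns))
  })
  lens <- vapply(struct, `[[`, numeric(1), "len")
  need <- sum(lens) + (config$n_genes + 1L) * config$min_gene_gap
  if (need > config$genome_length) {
    stop("genes cannot be placed without overlap: need ", need,
         " bases, genome has ", config$genome_length)
  }
  slack <- config$genome_length - need
  w <- runif(config$n_genes + 1L)
  extra <- floor(slack * w / sum(w))
  gaps <- config$min_gene_gap + extra
  starts <- cumsum(c(gaps[1] + 1, head(lens + gaps[-1], -1)))

  genes <- rbindlist(lapply(seq_len(config$n_genes), function(i) {
    st <- struct[[i]]
    ex_start <- starts[i] +
      cumsum(c(0, head(st$exons, -1) + st$introns))
    data.table(gene_id = sprintf("g%03d", i),
               exon_rank = seq_along(st$exons),
               start = as.integer(ex_start),
               end = as.integer(ex_start + st$exons - 1L))
  }))
  list(seq = seq, seqname = config$seqname, genes = genes)
}

#' Draw the circRNA truth set from the gene models
#'
#' Samples `config$n_circ` circles with exact subtype counts (largest
#' remainder rounding of `subtype_mix`). `multi_exon` circles splice a run
#' of consecutive exons; `single_exon` circles are one exon of at least
#' one read length; `small` circles are one exon shorter than the read;
#' `intron_retained` circles keep the genomic span of two consecutive
#' exons including the intron; `short_flank` circles are multi-exon with a
#' first exon shorter than the read. Junction boundaries always fall on
#' exon (or retained-intron) edges. A subtype that cannot be placed after
#' bounded resampling is an error.
#'
#' @param genes Gene models from [generate_genome()].
#' @param config A [sim_config()].
#' @return A `data.table` of truth records: `circ_id`, `chrom`, `start`
#'   (acceptor), `end` (donor), `subtype`, `circ_length`, and a `segments`
#'   list column of genomic intervals in splicing order.
#' @export
sample_circRNAs <- function(genes, config) {
  counts <- subtype_counts(config$subtype_mix, config$n_circ)
  gids <- unique(genes$gene_id)
  if (length(gids) == 0L && config$n_circ > 0L) {
    stop("no gene models to draw circRNAs from")
  }
  gene_list <- split(genes, by = "gene_id", sorted = FALSE)
  used <- character(0)
  out <- vector("list", config$n_circ)
  k <- 0L
  for (sub in names(counts)) {
    for (j in seq_len(counts[[sub]])) {
      seg <- NULL
      for (try in seq_len(200L)) {
        ex <- gene_list[[sample(length(gene_list), 1L)]]
        seg <- draw_subtype(ex, sub, config$read_len)
        if (!is.null(seg)) {
          key <- paste(seg$start[1], seg$end[nrow(seg)])
          if (key %in% used) seg <- NULL else break
        }
      }
      if (is.null(seg)) {
        stop("could not place a '", sub, "' circRNA after bounded retries; ",
             "check exon_length_range against read_len")
      }
      used <- c(used, paste(seg$start[1], seg$end[nrow(seg)]))
      k <- k + 1L
      out[[k]] <- data.table(
        circ_id = sprintf("circ%03d", k),
        chrom = config$seqname,
        start = seg$start[1],
        end = seg$end[nrow(seg)],
        subtype = sub,
        circ_length = sum(seg$end - seg$start + 1L),
        segments = list(seg))
    }
  }
  rbindlist(out)
}

subtype_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.list(base)
}

draw_subtype <- function(ex, sub, read_len) {
  n_ex <- nrow(ex)
  elen <- ex$end - ex$start + 1L
  pick_seg <- function(i, j) ex[i:j, .(start, end)]
  switch(sub,
    multi_exon = {
      if (n_ex < 2L) return(NULL)
      i <- sample(n_ex - 1L, 1L)
      j <- i + sample(n_ex - i, 1L)
      pick_seg(i, j)
    },
    single_exon = {
      ok <- which(elen >= read_len)
      if (!length(ok)) return(NULL)
      i <- ok[sample(length(ok), 1L)]
      pick_seg(i, i)
    },
    small = {
      ok <- which(elen < read_len & elen >= 20L)
      if (!length(ok)) return(NULL)
      i <- ok[sample(length(ok), 1L)]
      pick_seg(i, i)
    },
    intron_retained = {
      if (n_ex < 2L) return(NULL)
      i <- sample(n_ex - 1L, 1L)
      data.table(start = ex$start[i], end = ex$end[i + 1L])
    },
    short_flank = {
      ok <- which(head(elen, -1L) < read_len)
      if (!length(ok)) return(NULL)
      i <- ok[sample(length(ok), 1L)]
      j <- i + sample(n_ex - i, 1L)
      pick_seg(i, j)
    },
    stop("unknown subtype: ", sub))
}

## transcripts (linear per gene + circular per truth record) as a list of
## lists with id, type, segments, circular, depth
build_transcripts <- function(genes, truth, config) {
  tr <- list()
  if (nrow(genes) > 0L && config$depth_linear > 0) {
    for (g in split(genes, by = "gene_id", sorted = TRUE)) {
      tr[[length(tr) + 1L]] <- list(
        id = g$gene_id[1], type = "linear",
        segments = g[, .(start, end)], circular = FALSE,
        depth = config$depth_linear)
    }
  }
  if (!is.null(truth) && nrow(truth) > 0L && config$depth_circ > 0) {
    for (i in seq_len(nrow(truth))) {
      tr[[length(tr) + 1L]] <- list(
        id = truth$circ_id[i], type = "circ",
        segments = truth$segments[[i]], circular = TRUE,
        depth = config$depth_circ)
    }
  }
  tr
}

transcript_seq <- function(genome_seq, segments) {
  paste(substring(genome_seq, segments$start, segments$end), collapse = "")
}

#' Simulate paired-end reads from circular and linear transcripts
#'
#' Fragment counts per transcript follow the coverage identity
#' `round(depth * transcript_length / (2 * read_len))`; fragment lengths
#' are normal (`insert_mean`, `insert_sd`) truncated below at the read
#' length. Circular transcripts are sampled with modular coordinates, so
#' BSJ reads and sub-read-length wrap-around reads arise naturally; linear
#' fragments are confined to the transcript. Each pair is oriented
#' forward-reverse with the forward read equally likely to be mate 1 or
#' mate 2. Substitution errors are applied per base at `error_rate`.
#'
#' @param truth Truth set from [sample_circRNAs()] (may be `NULL`).
#' @param genes Gene models from [generate_genome()].
#' @param genome_seq Genome string from [generate_genome()].
#' @param config A [sim_config()].
#' @param outdir If non-`NULL`, write `reads_1.fq`, `reads_2.fq` and
#'   `truth.tsv` there.
#' @return A `data.table` of reads: `qname`, `mate_index`, `origin`,
#'   `origin_id`, `trans_idx`, `tstart` (1-based transcript coordinate),
#'   `strand`, `seq` (reference orientation, errors applied), `rlen`.
#' @export
simulate_reads <- function(truth, genes, genome_seq, config,
                           outdir = NULL) {
  tr <- build_transcripts(genes, truth, config)
  n <- config$read_len
  reads <- vector("list", length(tr))
  for (ti in seq_along(tr)) {
    t <- tr[[ti]]
    L <- sum(t$segments$end - t$segments$start + 1L)
    n_pairs <- round(t$depth * L / (2 * n))
    if (n_pairs < 1L) next
    if (!t$circular && L < n) next
    if (!t$circular && config$insert_mean < n) {
      stop("insert_mean below read_len is not allowed for linear ",
           "transcripts")
    }
    frag <- pmax(n, round(rnorm(n_pairs, config$insert_mean,
                                config$insert_sd)))
    if (t$circular) {
      fstart <- floor(runif(n_pairs) * L) + 1
    } else {
      frag <- pmin(frag, L)
      fstart <- floor(runif(n_pairs) * (L - frag + 1)) + 1
    }
    t_fwd <- fstart
    t_rev <- fstart + frag - n
    if (t$circular) {
      t_fwd <- ((t_fwd - 1) %% L) + 1
      t_rev <- ((t_rev - 1) %% L) + 1
    }
    flip <- runif(n_pairs) < 0.5
    qn <- sprintf("%s_f%05d", t$id, seq_len(n_pairs))
    reads[[ti]] <- data.table(
      qname = rep(qn, 2L),
      mate_index = c(ifelse(flip, 2L, 1L), ifelse(flip, 1L, 2L)),
      origin = t$type, origin_id = t$id, trans_idx = ti,
      tstart = as.integer(c(t_fwd, t_rev)),
      strand = rep(c("+", "-"), each = n_pairs),
      rlen = n)
  }
  reads <- rbindlist(reads)
  if (nrow(reads) == 0L) {
    reads[, seq := character(0)]
    return(reads)
  }

  ## reference-orientation sequences (transcripts all lie on +)
  reads[, seq := {
    t <- tr[[trans_idx[1]]]
    base <- transcript_seq(genome_seq, t$segments)
    L <- nchar(base)
    rep_needed <- if (t$circular) ceiling((L + n - 1) / L) else 1L
    tpl <- if (rep_needed > 1L) strrep(base, rep_needed) else base
    substring(tpl, tstart, tstart + n - 1L)
  }, by = trans_idx]

  reads <- apply_substitution_errors(reads, config$error_rate)
  setorder(reads, qname, mate_index)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fastq_pair(reads, outdir)
    write_truth(truth, reads, file.path(outdir, "truth.tsv"))
  }
  reads[]
}

apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  n_err <- rbinom(nrow(reads), reads$rlen, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(reads$rlen[i], n_err[i])
    s <- reads$seq[i]
    for (p in pos) {
      old <- substring(s, p, p)
      substring(s, p, p) <- sample(setdiff(bases, old), 1L)
    }
    set(reads, i, "seq", s)
  }
  reads
}

write_fastq_pair <- function(reads, outdir) {
  for (m in 1:2) {
    sub <- reads[mate_index == m]
    rseq <- sub$seq
    flipme <- sub$strand == "-"
    rseq[flipme] <- revcomp(rseq[flipme])
    dna <- Biostrings::DNAStringSet(rseq)
    names(dna) <- paste0(sub$qname, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", sub$rlen))
    Biostrings::writeXStringSet(
      dna, file.path(outdir, sprintf("reads_%d.fq", m)),
      format = "fastq", qualities = qual)
  }
}

write_truth <- function(truth, reads, path) {
  if (is.null(truth) || nrow(truth) == 0L) {
    fwrite(data.table(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      subtype = character(0), length = integer(0),
                      n_reads = integer(0)), path, sep = "\t")
    return(invisible(path))
  }
  cnt <- reads[origin == "circ", .N, by = origin_id]
  tab <- data.table(circ_id = truth$circ_id, chrom = truth$chrom,
                    start = truth$start, end = truth$end,
                    subtype = truth$subtype, length = truth$circ_length)
  tab[, n_reads := cnt$N[match(circ_id, cnt$origin_id)]]
  tab[is.na(n_reads), n_reads := 0L]
  fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Emit simplified split alignments as a SAM file
#'
#' Stands in for an external split-read aligner on the simulator's own
#' reads, whose true genomic paths are known. A read lying inside one
#' genomic segment becomes a single full-match record. A read crossing a
#' junction is soft-clipped and anchored on its longest genomic segment;
#' every other segment of at least `config$split_min` bases yields a
#' supplementary soft-clipped record, while shorter split segments are
#' dropped (the unbalanced-split pathology of real aligners). A read
#' wrapping a circle shorter than itself collapses onto the
#' clipped-both-ends three-segment record of the full circle. Mates carry
#' correct RNEXT/PNEXT/strand flags; MAPQ is 60 throughout.
#'
#' @param reads Read table from [simulate_reads()].
#' @param genes,truth Gene models and truth set the reads were drawn from.
#' @param config The [sim_config()] used.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
emit_alignments <- function(reads, genes, truth, config, path) {
  tr <- build_transcripts(genes, truth, config)
  reads <- copy(reads)
  reads[, .row := .I]
  pieces <- vector("list", length(tr))
  for (ti in seq_along(tr)) {
    sub <- reads[trans_idx == ti]
    if (nrow(sub) == 0L) next
    pc <- as.data.table(.read_pieces_cpp(
      sub$tstart, config$read_len,
      tr[[ti]]$segments$start, tr[[ti]]$segments$end,
      tr[[ti]]$circular))
    pc[, read_row := sub$.row[read_row]]
    pieces[[ti]] <- pc
  }
  pc <- rbindlist(pieces)
  if (nrow(pc) == 0L) {
    stop("no reads map to any transcript of this configuration")
  }
  pc <- pc[keep == 1L]
  setorder(pc, read_row, -len, roff)
  pc[, is_primary := !duplicated(read_row)]
  pc <- pc[is_primary | len >= config$split_min]

  info <- reads[pc$read_row]
  n <- config$read_len
  tail_s <- n - pc$roff - pc$len
  cigar <- paste0(ifelse(pc$roff > 0L, paste0(pc$roff, "S"), ""),
                  pc$len, "M",
                  ifelse(tail_s > 0L, paste0(tail_s, "S"), ""))

  prim <- pc[is_primary == TRUE]
  prim_info <- reads[prim$read_row]
  mate_pos <- prim$gstart[match(paste(info$qname, 3L - info$mate_index),
                                paste(prim_info$qname,
                                      prim_info$mate_index))]
  mate_strand_neg <- info$strand == "+" # FR: mate is on the other strand

  flag <- 1L +
    ifelse(info$strand == "-", 16L, 0L) +
    ifelse(mate_strand_neg, 32L, 0L) +
    ifelse(info$mate_index == 1L, 64L, 128L) +
    ifelse(pc$is_primary, 0L, 2048L)

  lines <- paste(info$qname, flag, config$seqname, pc$gstart, 60L, cigar,
                 "=", mate_pos, 0L, info$seq, strrep("I", n), sep = "\t")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", config$seqname, "\tLN:",
                     config$genome_length),
              "@PG\tID:circjunction_sim\tPN:circjunction")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run the full simulator and write every artefact
#'
#' Convenience wrapper: genome, gene models, circRNA truth set, paired
#' FASTQ, truth list, and the SAM alignments, all deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed). Files written:
#'   `genome.fa`, `genes.gtf`, `reads_1.fq`, `reads_2.fq`, `truth.tsv`,
#'   `alignments.sam`.
#' @return Invisibly, a list with `paths`, `truth`, `reads`, `genes`,
#'   `genome` and `config`.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  truth <- if (config$n_circ > 0L) sample_circRNAs(gen$genes, config)
           else NULL
  reads <- simulate_reads(truth, gen$genes, gen$seq, config,
                          outdir = outdir)

  fa <- Biostrings::DNAStringSet(gen$seq)
  names(fa) <- gen$seqname
  Biostrings::writeXStringSet(fa, file.path(outdir, "genome.fa"))
  write_gtf(gen$genes, config$seqname, file.path(outdir, "genes.gtf"))

  sam <- file.path(outdir, "alignments.sam")
  emit_alignments(reads, gen$genes, truth, config, sam)

  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "genes.gtf"),
    fastq1 = file.path(outdir, "reads_1.fq"),
    fastq2 = file.path(outdir, "reads_2.fq"),
    truth = file.path(outdir, "truth.tsv"),
    sam = sam)
  invisible(list(paths = paths, truth = truth, reads = reads,
                 genes = gen$genes, genome = gen$seq, config = config))
}

write_gtf <- function(genes, seqname, path) {
  if (nrow(genes) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = "+",
    type = "exon",
    source = "circjunction_sim",
    gene_id = genes$gene_id,
    transcript_id = paste0(genes$gene_id, ".t1"),
    exon_number = genes$exon_rank)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
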