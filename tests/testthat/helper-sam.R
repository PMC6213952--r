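## Build small SAM fixtures in code. Records are lists with named fields;
## unspecified fields fall back to sensible paired-end defaults.

sam_record <- function(qname = "r1", flag = 65L, rname = "chr1",
                       pos = 1000L, mapq = 60L, cigar = "100M",
                       rnext = "=", pnext = 2000L, tlen = 0L,
                       seq = strrep("A", 100L), qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
        qual, sep = "\t")
}

write_sam <- function(records, path = tempfile(fileext = ".sam"),
                      sq = c(chr1 = 1000000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(sq), "\tLN:", sq))
  writeLines(c(header, records), path)
  path
}

## FLAG helper: paired read with the usual bits
sam_flag <- function(mate = 1L, reverse = FALSE, mate_reverse = TRUE,
                     secondary = FALSE, supplementary = FALSE,
                     duplicate = FALSE, qcfail = FALSE, unmapped = FALSE,
                     mate_unmapped = FALSE) {
  1L +
    (if (unmapped) 4L else 0L) +
    (if (mate_unmapped) 8L else 0L) +
    (if (reverse) 16L else 0L) +
    (if (mate_reverse) 32L else 0L) +
    (if (mate == 1L) 64L else 128L) +
    (if (secondary) 256L else 0L) +
    (if (qcfail) 512L else 0L) +
    (if (duplicate) 1024L else 0L) +
    (if (supplementary) 2048L else 0L)
}

## A minimal two-circle-read fixture on a deterministic 3 kb reference:
## `n_bsj` forward BSJ reads (left records at the acceptor) and `n_bsj`
## reverse BSJ reads (right records at the donor), mates inside the circle.
## Returns list(path, acceptor, donor).
bsj_fixture <- function(n_bsj = 2L, acceptor = 1000L, donor = 1999L,
                        read_len = 100L, genome = NULL,
                        split = NULL) {
  set.seed(42)
  if (is.null(genome)) genome <- random_dna(3000L)
  circ <- substring(genome, acceptor, donor)
  L <- nchar(circ)
  circ2 <- paste0(circ, circ)
  recs <- character(0)
  if (is.null(split)) split <- 30L + 5L * seq_len(n_bsj)
  for (i in seq_len(n_bsj)) {
    k <- split[i]                       # donor-side bases of the + read
    sq <- substring(circ2, L - k + 1, L - k + read_len)
    recs <- c(recs,
      ## + read, record anchored at the acceptor: kS (n-k)M
      sam_record(qname = sprintf("fwd%02d", i), flag = sam_flag(1L),
                 pos = acceptor, cigar = sprintf("%dS%dM", k, read_len - k),
                 pnext = acceptor + 50L, seq = sq),
      ## its mate inside the circle, unclipped
      sam_record(qname = sprintf("fwd%02d", i),
                 flag = sam_flag(2L, reverse = TRUE, mate_reverse = FALSE),
                 pos = acceptor + 50L, cigar = sprintf("%dM", read_len),
                 pnext = acceptor,
                 seq = substring(genome, acceptor + 50L,
                                 acceptor + 49L + read_len)))
    ## - read, record anchored at the donor: (n-k)M kS
    k2 <- split[i] + 2L                 # acceptor-side bases of the - read
    sq2 <- substring(circ2, L - (read_len - k2) + 1, L - (read_len - k2) + read_len)
    recs <- c(recs,
      sam_record(qname = sprintf("rev%02d", i),
                 flag = sam_flag(1L, reverse = TRUE, mate_reverse = FALSE),
                 pos = donor - (read_len - k2) + 1L,
                 cigar = sprintf("%dM%dS", read_len - k2, k2),
                 pnext = acceptor + 20L, seq = sq2),
      sam_record(qname = sprintf("rev%02d", i),
                 flag = sam_flag(2L, reverse = FALSE, mate_reverse = TRUE),
                 pos = acceptor + 20L, cigar = sprintf("%dM", read_len),
                 pnext = donor - (read_len - k2) + 1L,
                 seq = substring(genome, acceptor + 20L,
                                 acceptor + 19L + read_len)))
  }
  list(path = write_sam(recs, sq = c(chr1 = 1000000L)),
       acceptor = acceptor, donor = donor, genome = genome)
}
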