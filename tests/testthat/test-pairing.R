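clip_read <- function(read_id = "r", mate_index = 1L, chrom = "chr1",
                      pos = 1000L, strand = "+", mapq = 60L,
                      cigar = "30S70M", sequence = strrep("A", 100),
                      mate_chrom = "chr1", mate_pos = 1500L,
                      mate_strand = "-", cluster = "LEFT") {
  cg <- parse_cigar(cigar)
  refw <- sum(cg$length[cg$op %in% c("M", "D", "N", "=", "X")])
  lead <- if (cg$op[1] %in% c("S", "H")) cg$length[1] else 0L
  trail <- if (cg$op[nrow(cg)] %in% c("S", "H")) cg$length[nrow(cg)] else 0L
  data.table::data.table(
    read_id = read_id, mate_index = mate_index, chrom = chrom, pos = pos,
    strand = strand, mapq = mapq, cigar = cigar, sequence = sequence,
    rlen = nchar(sequence), left_clip = lead, right_clip = trail,
    match_start = pos, match_end = pos + refw - 1L,
    mate_chrom = mate_chrom, mate_pos = mate_pos,
    mate_strand = mate_strand, cluster = cluster)
}

test_that("mate_consistent enforces region, orientation and chromosome", {
  left <- clip_read(strand = "+", pos = 1000L, mate_pos = 1500L,
                    mate_strand = "-")
  expect_true(mate_consistent(left, c(1000, 2000), side = "left"))
  ## equal directions rejected
  same_dir <- clip_read(strand = "+", mate_strand = "+")
  expect_false(mate_consistent(same_dir, c(1000, 2000), side = "left"))
  ## different chromosome rejected
  off_chrom <- clip_read(mate_chrom = "chr2")
  expect_false(mate_consistent(off_chrom, c(1000, 2000), side = "left"))
  ## mate outside the putative circle rejected; boundaries inclusive
  expect_false(mate_consistent(left, c(1000, 1400), side = "left"))
  expect_true(mate_consistent(left, c(1000, 1500), side = "left"))
  ## right-cluster reads need the mirrored orientation
  right <- clip_read(strand = "-", cigar = "70M30S", pos = 1931L,
                     mate_pos = 1200L, mate_strand = "+",
                     cluster = "RIGHT")
  expect_true(mate_consistent(right, c(1000, 2000), side = "right"))
  expect_false(mate_consistent(right, c(1300, 2000), side = "right"))
  ## unplaced mate is never consistent
  nomate <- clip_read(mate_pos = NA_integer_, mate_chrom = NA_character_)
  expect_false(mate_consistent(nomate, c(1000, 2000), side = "left"))
  ## RF layout swaps the strand expectations
  rf_left <- clip_read(strand = "-", mate_strand = "+")
  expect_true(mate_consistent(rf_left, c(1000, 2000), side = "left",
                              layout = "rf"))
  expect_false(mate_consistent(rf_left, c(1000, 2000), side = "left"))
})

test_that("infer_junction does the SAM arithmetic", {
  j1 <- infer_junction(clip_read(pos = 1000L, cigar = "30S70M"),
                       clip_read(pos = 1931L, cigar = "70M30S",
                                 strand = "-", cluster = "RIGHT"))
  expect_identical(j1[c("acceptor", "donor")], list(acceptor = 1000L,
                                                    donor = 2000L))
  j2 <- infer_junction(clip_read(pos = 500L, cigar = "10S90M"),
                       clip_read(pos = 500L, cigar = "90M10S",
                                 strand = "-", cluster = "RIGHT"))
  expect_identical(j2$donor, 589L)
  j3 <- infer_junction(clip_read(pos = 100L, cigar = "50S50M"),
                       clip_read(pos = 120L, cigar = "50M50S",
                                 strand = "-", cluster = "RIGHT"))
  expect_identical(j3[c("acceptor", "donor")], list(acceptor = 100L,
                                                    donor = 169L))
  expect_error(infer_junction(clip_read(chrom = "chr1"),
                              clip_read(chrom = "chr2", cluster = "RIGHT")))
})

test_that("enumerate_pairs applies the four pairing restrictions", {
  left <- clip_read("l1", pos = 1000L, mate_pos = 1500L)
  right <- clip_read("r1", pos = 1931L, cigar = "70M30S", strand = "-",
                     mate_pos = 1200L, mate_strand = "+", cluster = "RIGHT")
  p <- enumerate_pairs(left, right)
  expect_identical(nrow(p), 1L)
  expect_identical(p$acceptor, 1000L)
  expect_identical(p$donor, 2000L)

  ## different chromosomes: no pair
  expect_identical(nrow(enumerate_pairs(left,
    clip_read("r2", chrom = "chr2", mate_chrom = "chr2", strand = "-",
              cigar = "70M30S", mate_strand = "+", cluster = "RIGHT"))), 0L)
  ## span above max_span: no pair
  expect_identical(nrow(enumerate_pairs(left, right, max_span = 500L)), 0L)
  ## left must be upstream of right
  far_left <- clip_read("l2", pos = 5000L, mate_pos = 5100L)
  expect_identical(nrow(enumerate_pairs(far_left, right)), 0L)
  ## low-mapq members excluded
  expect_identical(nrow(enumerate_pairs(
    clip_read("l3", mapq = 3L, mate_pos = 1500L), right,
    min_mapq_pair = 10L)), 1L - 1L)
  ## a record never pairs with the other record of the same sequenced read
  self_r <- clip_read("l1", pos = 1931L, cigar = "70M30S", strand = "-",
                      mate_pos = 1200L, mate_strand = "+",
                      cluster = "RIGHT")
  expect_identical(nrow(enumerate_pairs(left, self_r)), 0L)
})

test_that("enumerate_pairs equals the brute-force cross product", {
  set.seed(101)
  for (rep in 1:10) {
    nl <- sample(3:8, 1)
    nr <- sample(3:8, 1)
    lefts <- data.table::rbindlist(lapply(seq_len(nl), function(i) {
      clip_read(sprintf("L%d", i), pos = sample(500:3000, 1),
                strand = sample(c("+", "-"), 1),
                mapq = sample(c(0L, 5L, 30L, 60L), 1),
                mate_pos = sample(500:3500, 1),
                mate_strand = sample(c("+", "-"), 1))
    }))
    rights <- data.table::rbindlist(lapply(seq_len(nr), function(i) {
      clip_read(sprintf("R%d", i), pos = sample(500:3000, 1),
                cigar = "70M30S",
                strand = sample(c("+", "-"), 1),
                mapq = sample(c(0L, 5L, 30L, 60L), 1),
                mate_pos = sample(500:3500, 1),
                mate_strand = sample(c("+", "-"), 1),
                cluster = "RIGHT")
    }))
    got <- enumerate_pairs(lefts, rights, max_span = 2000L,
                           min_mapq_pair = 10L)
    ## brute force: every left x right against the spec's restrictions
    want <- 0L
    for (i in seq_len(nl)) for (j in seq_len(nr)) {
      l <- lefts[i]; r <- rights[j]
      span <- c(l$match_start, r$match_end)
      ok <- l$chrom == r$chrom &&
        l$match_start <= r$match_end &&
        (r$match_end - l$match_start + 1L) <= 2000L &&
        l$mapq >= 10L && r$mapq >= 10L &&
        mate_consistent(l, span, side = "left") &&
        mate_consistent(r, span, side = "right")
      if (ok) {
        want <- want + 1L
        expect_true(nrow(got[left_read_id == l$read_id &
                             right_read_id == r$read_id]) == 1L)
      }
    }
    expect_identical(nrow(got), want)
    ## monotonicity: loosening thresholds yields a superset
    loose <- enumerate_pairs(lefts, rights, max_span = 10000000L,
                             min_mapq_pair = 0L)
    expect_true(all(paste(got$left_read_id, got$right_read_id) %in%
                    paste(loose$left_read_id, loose$right_read_id)))
  }
})

test_that("a fully consistent 2x3 cluster yields all 6 pairs", {
  lefts <- data.table::rbindlist(lapply(1:2, function(i) {
    clip_read(sprintf("L%d", i), pos = 1000L + i, mate_pos = 1500L)
  }))
  rights <- data.table::rbindlist(lapply(1:3, function(i) {
    clip_read(sprintf("R%d", i), pos = 1931L + i, cigar = "70M30S",
              strand = "-", mate_pos = 1200L, mate_strand = "+",
              cluster = "RIGHT")
  }))
  expect_identical(nrow(enumerate_pairs(lefts, rights)), 6L)
})
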