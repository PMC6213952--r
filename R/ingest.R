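#' Extract clipped reads from a SAM/BAM file and assign junction clusters
#'
#' Reads every alignment record (including secondary and supplementary
#' records, since split alignments carry the junction signal), drops
#' duplicates (0x400), QC failures (0x200) and unplaced (0x4) records, and
#' keeps records whose CIGAR clip classifies them as potential BSJ evidence
#' (see [classify_alignment()]). Records clipped on both ends contribute to
#' both clusters. Each alignment record of a multi-mapped read is considered
#' separately. Hard-clipped records have their full sequence recovered from
#' the same read's primary record when available; otherwise they are dropped
#' and counted.
#'
#' @param path Path to a SAM or BAM file (SAM is converted internally).
#' @param min_clip Minimum clip length (bases) for cluster membership.
#' @param min_mapq Minimum mapping quality at ingestion; the stricter
#'   reliable-mapping filter is applied later at candidate level.
#' @param verbose Emit per-stage counts via `message()`.
#' @return A list with elements `left` and `right` (`data.table`s of clipped
#'   records, one row per record-cluster membership, with columns `read_id`,
#'   `mate_index`, `chrom`, `pos`, `strand`, `mapq`, `cigar`, `sequence`,
#'   `rlen`, `left_clip`, `right_clip`, `match_start`, `match_end`,
#'   `mate_chrom`, `mate_pos`, `mate_strand`, `cluster`) and
#'   `n_dropped_hardclip` (hard-clipped records whose sequence could not be
#'   recovered).
#' @export
extract_clipped_reads <- function(path, min_clip = 10L, min_mapq = 1L,
                                  verbose = FALSE) {
  rec <- read_alignments(path)
  if (verbose) message("alignment records: ", nrow(rec))

  rec <- rec[bitwAnd(flag, 0x4L) == 0L &
             bitwAnd(flag, 0x200L) == 0L &
             bitwAnd(flag, 0x400L) == 0L &
             cigar != "*" & !is.na(pos)]
  rec <- rec[mapq >= min_mapq]

  cg <- decompose_cigars(rec$cigar)
  rec[, `:=`(left_clip = cg$lead, right_clip = cg$trail,
             rlen = cg$readw,
             match_start = pos,
             match_end = pos + cg$refw - 1L)]
  rec <- rec[cg$refw > 0L]

  lead_ok  <- rec$left_clip >= min_clip
  trail_ok <- rec$right_clip >= min_clip
  rec[, cluster := ifelse(lead_ok & trail_ok, "BOTH",
                   ifelse(lead_ok, "LEFT",
                   ifelse(trail_ok, "RIGHT", "NONE")))]
  rec <- rec[cluster != "NONE"]

  ## recover full sequences for hard-clipped records from the primary record
  n_dropped <- 0L
  hard <- grepl("H", rec$cigar, fixed = TRUE)
  if (any(hard)) {
    prim <- rec_primaries(path)
    hidx <- which(hard)
    key <- paste(rec$read_id[hidx], rec$mate_index[hidx])
    hit <- match(key, paste(prim$read_id, prim$mate_index))
    ok <- !is.na(hit)
    if (any(ok)) {
      pseq <- prim$sequence[hit[ok]]
      flip <- prim$strand[hit[ok]] != rec$strand[hidx[ok]]
      pseq[flip] <- revcomp(pseq[flip])
      rec$sequence[hidx[ok]] <- pseq
    }
    n_dropped <- sum(!ok)
    if (n_dropped > 0L) {
      message(n_dropped,
              " hard-clipped record(s) dropped: no primary sequence")
      rec <- rec[-hidx[!ok]]
    }
  }

  keepcols <- c("read_id", "mate_index", "chrom", "pos", "strand", "mapq",
                "cigar", "sequence", "rlen", "left_clip", "right_clip",
                "match_start", "match_end", "mate_chrom", "mate_pos",
                "mate_strand", "cluster")
  rec <- rec[, keepcols, with = FALSE]

  left  <- rec[cluster %in% c("LEFT", "BOTH")]
  right <- rec[cluster %in% c("RIGHT", "BOTH")]
  setorder(left, chrom, match_start, match_end, read_id, mate_index, cigar)
  setorder(right, chrom, match_start, match_end, read_id, mate_index, cigar)
  left[, idx := .I]
  right[, idx := .I]
  if (verbose) {
    message("left-junction cluster: ", nrow(left),
            "; right-junction cluster: ", nrow(right))
  }
  list(left = left, right = right, n_dropped_hardclip = n_dropped)
}

## Read all records of a SAM/BAM file into a data.table via Rsamtools.
read_alignments <- function(path) {
  bam <- as_bam_path(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "seq")
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  data.table(
    read_id    = res$qname,
    flag       = flag,
    chrom      = as.character(res$rname),
    pos        = res$pos,
    strand     = ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
    mapq       = as.integer(res$mapq),
    cigar      = res$cigar,
    sequence   = as.character(res$seq),
    mate_index = ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 1L),
    mate_chrom = ifelse(bitwAnd(flag, 0x8L) > 0L, NA_character_,
                        as.character(res$mrnm)),
    mate_pos   = ifelse(bitwAnd(flag, 0x8L) > 0L, NA_integer_, res$mpos),
    mate_strand = ifelse(bitwAnd(flag, 0x8L) > 0L, NA_character_,
                         ifelse(bitwAnd(flag, 0x20L) > 0L, "-", "+"))
  )
}

as_bam_path <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

## primary records (neither secondary nor supplementary) with their sequence
rec_primaries <- function(path) {
  rec <- read_alignments(path)
  rec <- rec[bitwAnd(flag, 0x900L) == 0L & sequence != "" &
             !grepl("H", cigar, fixed = TRUE)]
  rec[, .(read_id, mate_index, sequence, strand)]
}

## Vectorised CIGAR decomposition: leading/trailing clip, reference width,
## full read width (hard clips included) for a character vector of CIGARs.
decompose_cigars <- function(cig) {
  toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))
  nt   <- lengths(toks)
  allt <- unlist(toks, use.names = FALSE)
  op   <- substring(allt, nchar(allt), nchar(allt))
  ln   <- as.integer(substring(allt, 1L, nchar(allt) - 1L))
  rid  <- rep.int(seq_along(toks), nt)

  is_sh  <- op %in% c("S", "H")
  refw  <- as.integer(rowsum_int(ln * (op %in% c("M", "D", "N", "=", "X")),
                                 rid, length(cig)))
  readw <- as.integer(rowsum_int(ln * (op %in% c("M", "I", "S", "H", "=", "X")),
                                 rid, length(cig)))

  first <- cumsum(nt) - nt + 1L
  last  <- cumsum(nt)
  lead <- integer(length(cig))
  sel <- nt >= 1L & is_sh[first]
  lead[sel] <- ln[first[sel]]
  sel2 <- sel & nt >= 2L & is_sh[pmin(first + 1L, last)] & (first + 1L) < last
  lead[sel2] <- lead[sel2] + ln[first[sel2] + 1L]

  trail <- integer(length(cig))
  selt <- nt >= 2L & is_sh[last]
  trail[selt] <- ln[last[selt]]
  selt2 <- selt & nt >= 3L & is_sh[pmax(last - 1L, first)] &
    (last - 1L) > first
  trail[selt2] <- trail[selt2] + ln[last[selt2] - 1L]

  list(lead = lead, trail = trail, refw = refw, readw = readw)
}

rowsum_int <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    agg <- rowsum(x, g)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

## reverse complement for plain character vectors (A/C/G/T/N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
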