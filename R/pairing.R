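#' Paired-end mapping (PEM) consistency of a junction read
#'
#' The two segments of a bona fide BSJ read delimit the circRNA, so its
#' mate must map inside the putative circle. For a forward-reverse (FR)
#' library a left-cluster (acceptor-side) junction read must be on the `+`
#' strand with its mate on `-` falling downstream inside the region; a
#' right-cluster (donor-side) read must be on `-` with its mate on `+`
#' upstream inside the region. Pairs with equal directions are rejected.
#' Region boundaries are inclusive. For RF libraries the strand
#' expectations are swapped.
#'
#' @param read A one-row clipped-read record (fields `chrom`, `strand`,
#'   `mate_chrom`, `mate_pos`, `mate_strand`).
#' @param span Numeric length-2 vector `(acceptor, donor)` of the putative
#'   circRNA region (1-based inclusive).
#' @param side `"left"` or `"right"`: which junction cluster the read is
#'   being used as. Defaults to the read's own `cluster` field when
#'   unambiguous.
#' @param layout Library layout, `"fr"` (default) or `"rf"`.
#' @return Logical scalar; `FALSE` when the mate is unplaced.
#' @export
mate_consistent <- function(read, span, side = NULL, layout = c("fr", "rf")) {
  layout <- match.arg(layout)
  if (is.null(side)) {
    side <- switch(as.character(read$cluster),
                   LEFT = "left", RIGHT = "right",
                   stop("side must be given for BOTH-cluster reads"))
  }
  side <- match.arg(side, c("left", "right"))
  if (is.na(read$mate_pos) || is.na(read$mate_chrom)) return(FALSE)
  if (read$mate_chrom != read$chrom) return(FALSE)

  exp_read <- if (side == "left") "+" else "-"
  if (layout == "rf") exp_read <- if (exp_read == "+") "-" else "+"
  exp_mate <- if (exp_read == "+") "-" else "+"
  if (read$strand != exp_read || read$mate_strand != exp_mate) return(FALSE)

  read$mate_pos >= span[1] && read$mate_pos <= span[2]
}

#' Infer the back-spliced junction implied by a left/right read pair
#'
#' The left-cluster read's matched segment starts at the circle's genomic
#' start (the 3' splice acceptor) and the right-cluster read's matched
#' segment ends at its genomic end (the 5' splice donor).
#'
#' @param left,right One-row clipped-read records from the left and right
#'   junction clusters.
#' @return A list with `chrom`, `acceptor`, `donor` (1-based inclusive).
#' @export
infer_junction <- function(left, right) {
  stopifnot(left$chrom == right$chrom,
            left$match_start <= right$match_end)
  list(chrom = left$chrom,
       acceptor = as.integer(left$match_start),
       donor = as.integer(right$match_end))
}

#' Enumerate candidate BSJ read pairs from the two junction clusters
#'
#' Emits every left x right pair satisfying the pairing restrictions: same
#' chromosome; the left read upstream of the right read; genomic span at
#' most `max_span`; both reads at or above `min_mapq_pair`; and both reads
#' PEM-consistent ([mate_consistent()]) with the pair's inferred junction
#' span. A read may participate in many pairs; the two records of one
#' sequenced read never pair with each other.
#'
#' @param left,right Cluster tables from [extract_clipped_reads()].
#' @param max_span Maximum circRNA genomic span in bases.
#' @param min_mapq_pair Minimum mapping quality of both pair members.
#' @param layout Library layout, `"fr"` or `"rf"`.
#' @return A `data.table` of candidate pairs with columns `chrom`,
#'   `acceptor`, `donor`, `left_idx`, `right_idx` (row indices into the
#'   cluster tables), read identifiers and member mapping qualities,
#'   ordered deterministically.
#' @export
enumerate_pairs <- function(left, right, max_span = 200000L,
                            min_mapq_pair = 10L, layout = c("fr", "rf")) {
  layout <- match.arg(layout)
  empty <- data.table(chrom = character(0), acceptor = integer(0),
                      donor = integer(0), left_idx = integer(0),
                      right_idx = integer(0),
                      left_read_id = character(0), left_mate = integer(0),
                      right_read_id = character(0), right_mate = integer(0),
                      left_mapq = integer(0), right_mapq = integer(0))
  if (nrow(left) == 0L || nrow(right) == 0L) return(empty)

  left <- ensure_idx(left)
  right <- ensure_idx(right)
  exp_l <- if (layout == "fr") "+" else "-"
  exp_r <- if (layout == "fr") "-" else "+"

  ## per-read PEM prechecks: everything not involving the partner
  L <- left[strand == exp_l & !is.na(mate_pos) & mate_chrom == chrom &
            mate_strand == exp_r & mapq >= min_mapq_pair &
            mate_pos >= match_start]
  R <- right[strand == exp_r & !is.na(mate_pos) & mate_chrom == chrom &
             mate_strand == exp_l & mapq >= min_mapq_pair &
             mate_pos <= match_end]
  if (nrow(L) == 0L || nrow(R) == 0L) return(empty)

  Lj <- L[, .(chrom,
              a = match_start,
              lo = pmax(match_start, mate_pos),
              hi = match_start + as.integer(max_span) - 1L,
              left_idx = idx, left_read_id = read_id,
              left_mate = mate_index, left_mapq = mapq)]
  Rj <- R[, .(chrom, match_end, mate_pos, right_idx = idx,
              right_read_id = read_id, right_mate = mate_index,
              right_mapq = mapq)]

  P <- Rj[Lj,
          on = .(chrom, match_end >= lo, match_end <= hi, mate_pos >= a),
          allow.cartesian = TRUE, nomatch = NULL,
          .(chrom = i.chrom, acceptor = i.a, donor = x.match_end,
            left_idx = i.left_idx, right_idx,
            left_read_id = i.left_read_id, left_mate = i.left_mate,
            right_read_id, right_mate,
            left_mapq = i.left_mapq, right_mapq)]
  P <- P[!(left_read_id == right_read_id & left_mate == right_mate)]
  setorder(P, chrom, acceptor, donor, left_idx, right_idx)
  P[]
}

ensure_idx <- function(dt) {
  dt <- as.data.table(dt)
  if (!"idx" %in% names(dt)) {
    dt <- copy(dt)
    dt[, idx := .I]
  }
  dt
}
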