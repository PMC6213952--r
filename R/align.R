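#' Nucleotide scoring scheme for local alignment
#'
#' @param match Reward for a matching column (> 0).
#' @param mismatch Penalty for a mismatching column (<= 0). `N` never
#'   matches and is always scored as a mismatch.
#' @param gap_open Penalty for the first column of a gap run (<= 0).
#' @param gap_extend Penalty for each further gap column (<= 0).
#' @return A list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L,
                           gap_open = -2L, gap_extend = -1L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Optimal local alignment of two reads
#'
#' Smith-Waterman dynamic programming with affine gap costs, used to decide
#' whether two clipped reads share a local similar sequence. When no
#' positive-scoring alignment exists the score is 0 and all intervals are
#' empty. Among equal-scoring optima the traceback is deterministic
#' (first maximal cell in row-major order; diagonal preferred over vertical
#' over horizontal moves).
#'
#' @param seq_a,seq_b Nucleotide strings (alphabet `A C G T N`), non-empty.
#' @param scoring A [scoring_scheme()].
#' @return A list of class `"local_alignment"` with elements `score`,
#'   `a_start`, `a_end`, `b_start`, `b_end` (1-based inclusive intervals),
#'   `mismatches`, `gaps` (gapped columns), `columns` (alignment length),
#'   `aligned_a`, `aligned_b` (gapped strings).
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")$score  # 8
#' @export
local_align <- function(seq_a, seq_b, scoring = scoring_scheme()) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("sequences must be non-empty")
  }
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b)) {
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  }
  res <- .sw_align_cpp(seq_a, seq_b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  structure(res, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("local alignment: score", x$score, "\n")
  if (x$score > 0) {
    cat("  a[", x$a_start, "-", x$a_end, "]  b[", x$b_start, "-", x$b_end,
        "]  columns=", x$columns, " mismatches=", x$mismatches,
        " gaps=", x$gaps, "\n", sep = "")
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Does a local alignment span both reads' clip boundaries?
#'
#' The shared similar sequence of two genuine BSJ reads contains bases from
#' both sides of each read's junction point. For the left-cluster read the
#' junction point sits between read positions `left_clip` and
#' `left_clip + 1` (reference orientation); for the right-cluster read,
#' between `rlen - right_clip` and `rlen - right_clip + 1`.
#'
#' @param result A [local_align()] result computed from
#'   `(left$sequence, right$sequence)`.
#' @param left,right One-row `data.table`s (or lists) of clipped reads with
#'   fields `left_clip`, `right_clip` and `rlen`.
#' @return `TRUE` iff the aligned interval on each read covers that read's
#'   clip boundary; `FALSE` for an empty (zero-score) alignment.
#' @export
spans_junction <- function(result, left, right) {
  if (result$score <= 0) return(FALSE)
  k1 <- as.integer(left$left_clip)
  k2 <- as.integer(right$rlen) - as.integer(right$right_clip)
  result$a_start <= k1 && result$a_end >= k1 + 1L &&
    result$b_start <= k2 && result$b_end >= k2 + 1L
}

#' Accept or reject a candidate BSJ read pair by local similarity
#'
#' Runs [local_align()] on the pair's two read sequences and accepts the
#' pair iff the optimal alignment is long enough, clean enough, and spans
#' the circular junction on both reads. Accepted pairs are putative BSJ
#' read pairs.
#'
#' @param pair A list with elements `left` and `right`, each a one-row
#'   clipped-read record (fields `sequence`, `left_clip`, `right_clip`,
#'   `rlen`).
#' @param scoring A [scoring_scheme()].
#' @param max_mismatch Maximum mismatching columns in the similar region.
#' @param max_gap Maximum gapped columns.
#' @param min_overlap Minimum alignment length (columns).
#' @return Logical scalar.
#' @export
accept_pair <- function(pair, scoring = scoring_scheme(),
                        max_mismatch = 2L, max_gap = 2L,
                        min_overlap = 15L) {
  res <- local_align(pair$left$sequence, pair$right$sequence, scoring)
  res$columns >= min_overlap &&
    res$mismatches <= max_mismatch &&
    res$gaps <= max_gap &&
    spans_junction(res, pair$left, pair$right)
}

#' Default mismatch/gap threshold for a read length
#'
#' Longer reads yield longer similar regions and proportionally more
#' sequencing-error mismatches, so the default threshold scales with read
#' length: `ceiling(0.02 * read_len)` (2 for 100 bp reads).
#'
#' @param read_len Read length in bases.
#' @return Integer threshold.
#' @export
mismatch_threshold <- function(read_len) {
  as.integer(ceiling(0.02 * read_len))
}

#' Batch-filter candidate pairs by local similarity
#'
#' Applies the [accept_pair()] decision to every row of a candidate-pair
#' table. A cheap ungapped screen at clip-consistent diagonal offsets
#' rejects clearly dissimilar pairs before the full dynamic program; the
#' decision for surviving pairs is the full Smith-Waterman criterion, so on
#' substitution-only data the result equals applying [accept_pair()] to
#' each pair.
#'
#' @param pairs Candidate pairs from [enumerate_pairs()].
#' @param left,right Cluster tables from [extract_clipped_reads()].
#' @inheritParams accept_pair
#' @return The accepted subset of `pairs`, with alignment statistics
#'   columns `score`, `mismatches`, `gaps`, `columns` appended.
#' @export
filter_candidate_pairs <- function(pairs, left, right,
                                   scoring = scoring_scheme(),
                                   max_mismatch = 2L, max_gap = 2L,
                                   min_overlap = 15L) {
  if (nrow(pairs) == 0L) {
    out <- copy(pairs)
    out[, `:=`(score = integer(0), mismatches = integer(0),
               gaps = integer(0), columns = integer(0))]
    return(out[])
  }
  res <- .batch_filter_cpp(
    left$sequence, left$left_clip,
    right$sequence, right$rlen - right$right_clip,
    pairs$left_idx, pairs$right_idx,
    scoring$match, scoring$mismatch, scoring$gap_open, scoring$gap_extend,
    as.integer(max_mismatch), as.integer(max_gap), as.integer(min_overlap))
  out <- pairs[res$accept]
  out[, `:=`(score = res$score[res$accept],
             mismatches = res$mismatches[res$accept],
             gaps = res$gaps[res$accept],
             columns = res$columns[res$accept])]
  out[]
}
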