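#' Cluster accepted BSJ read pairs by junction locus
#'
#' Sequencing errors and fortuitously matching bases can shift the apparent
#' junction boundary by a few bases, so raw junctions are merged by
#' single-linkage clustering: two junctions link iff they are on the same
#' chromosome and both boundary differences are at most `tolerance`. The
#' representative junction of a cluster is the modal (most frequent by
#' supporting pair count) member junction, ties broken by smallest
#' `(acceptor, donor)`.
#'
#' Every read of an accepted pair carries a similar region spanning the
#' back-spliced junction, i.e. bases on both sides of each splice site, so
#' each distinct read name supports both the acceptor and the donor site:
#' `support_left` and `support_right` both equal the distinct supporting
#' read-name count. Per-side member counts are reported as `n_left` /
#' `n_right`.
#'
#' @param pairs Accepted pairs from [filter_candidate_pairs()] (columns
#'   `chrom`, `acceptor`, `donor`, `left_read_id`, `right_read_id`,
#'   `left_idx`, `right_idx`, `left_mapq`, `right_mapq`).
#' @param tolerance Maximum per-boundary distance (bases) for linkage.
#' @return A `data.table` of candidates: `chrom`, `acceptor`, `donor`,
#'   `bsj_count` (distinct read names), `support_left`, `support_right`,
#'   `n_left`, `n_right`, `mean_mapq` (mean over distinct supporting
#'   records), `circ_id`, and a `member_junctions` list column.
#' @export
cluster_junctions <- function(pairs, tolerance = 5L) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_candidates())
  pairs <- as.data.table(pairs)

  J <- pairs[, .(npairs = .N), by = .(chrom, acceptor, donor)]
  J[, jid := .I]
  tol <- as.integer(tolerance)
  Ja <- J[, .(chrom, alo = acceptor - tol, ahi = acceptor + tol,
              dlo = donor - tol, dhi = donor + tol, jid_a = jid)]
  E <- J[Ja, on = .(chrom, acceptor >= alo, acceptor <= ahi,
                    donor >= dlo, donor <= dhi),
         allow.cartesian = TRUE, nomatch = NULL,
         .(from = i.jid_a, to = x.jid)]
  comp <- union_find(nrow(J), E$from, E$to)
  J[, cl := comp]

  pairs <- J[, .(chrom, acceptor, donor, cl)][pairs,
    on = .(chrom, acceptor, donor)]

  out <- pairs[, cluster_summary(.SD), by = cl]
  out[, cl := NULL]
  setorder(out, chrom, acceptor, donor)
  out[, circ_id := sprintf("%s:%d|%d", chrom, acceptor, donor)]
  out[]
}

cluster_summary <- function(sd) {
  ## modal raw junction, ties to the smallest (acceptor, donor)
  tab <- sd[, .(n = .N), by = .(acceptor, donor)]
  setorder(tab, -n, acceptor, donor)
  reads <- unique(c(sd$left_read_id, sd$right_read_id))
  if (all(c("left_idx", "right_idx") %in% names(sd))) {
    rec_mapq <- c(sd$left_mapq[!duplicated(sd$left_idx)],
                  sd$right_mapq[!duplicated(sd$right_idx)])
  } else {
    rec_mapq <- c(sd$left_mapq[!duplicated(sd$left_read_id)],
                  sd$right_mapq[!duplicated(sd$right_read_id)])
  }
  data.table(
    chrom = sd$chrom[1L],
    acceptor = tab$acceptor[1L],
    donor = tab$donor[1L],
    bsj_count = length(reads),
    support_left = length(reads),
    support_right = length(reads),
    n_left = uniqueN(sd$left_read_id),
    n_right = uniqueN(sd$right_read_id),
    mean_mapq = mean(rec_mapq),
    member_junctions = list(tab[, .(acceptor, donor, n)]))
}

empty_candidates <- function() {
  data.table(chrom = character(0), acceptor = integer(0),
             donor = integer(0), bsj_count = integer(0),
             support_left = integer(0), support_right = integer(0),
             n_left = integer(0), n_right = integer(0),
             mean_mapq = numeric(0), member_junctions = list(),
             circ_id = character(0))
}

## union-find with path halving; edges given as two integer vectors
union_find <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k])
    b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Final support and mapping-quality filters
#'
#' Keeps exactly the candidates with at least `min_side_support` reads
#' supporting each splice site and a mean supporting-record mapping
#' quality of at least `min_mean_mapq`.
#'
#' @param candidates Candidate table from [cluster_junctions()].
#' @param min_side_support Minimum distinct supporting reads per splice
#'   site.
#' @param min_mean_mapq Minimum mean mapping quality of supporting records.
#' @return The filtered candidate table.
#' @export
apply_final_filters <- function(candidates, min_side_support = 2L,
                                min_mean_mapq = 10) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates[support_left >= min_side_support &
             support_right >= min_side_support &
             mean_mapq >= min_mean_mapq]
}

#' Detect circRNAs from a SAM/BAM file
#'
#' Runs the full four-stage pipeline: clipped-read extraction and
#' classification, PEM filtering and pair enumeration, local-similarity
#' identification of BSJ read pairs, and junction clustering with final
#' support/quality filters.
#'
#' @param sam_path Path to the aligned reads (SAM or BAM).
#' @param min_clip Minimum clip length for cluster membership (bases).
#' @param min_mapq Mapping-quality floor at ingestion.
#' @param max_span Maximum circRNA genomic span (bases).
#' @param min_mapq_pair Mapping-quality floor for pair members.
#' @param scoring A [scoring_scheme()] for the local alignment.
#' @param max_mismatch,max_gap Similar-region thresholds; `NULL` scales
#'   with the observed read length as [mismatch_threshold()].
#' @param min_overlap Minimum similar-region length (columns).
#' @param tolerance Junction clustering tolerance (bases).
#' @param min_side_support,min_mean_mapq Final filters, see
#'   [apply_final_filters()].
#' @param layout Library layout (`"fr"` or `"rf"`).
#' @param partitions Number of chunks the candidate-pair table is split
#'   into for filtering. The filter is a pure per-pair function, so the
#'   output is identical for any partitioning; the argument exists to
#'   bound per-chunk memory and to mirror multi-worker execution.
#' @param verbose Log per-stage counts.
#' @return A candidate `data.table` (see [cluster_junctions()]), possibly
#'   empty.
#' @export
detect_circRNAs <- function(sam_path, min_clip = 10L, min_mapq = 1L,
                            max_span = 200000L, min_mapq_pair = 10L,
                            scoring = scoring_scheme(),
                            max_mismatch = NULL, max_gap = NULL,
                            min_overlap = 15L, tolerance = 5L,
                            min_side_support = 2L, min_mean_mapq = 10,
                            layout = c("fr", "rf"), partitions = 1L,
                            verbose = FALSE) {
  layout <- match.arg(layout)
  clusters <- extract_clipped_reads(sam_path, min_clip = min_clip,
                                    min_mapq = min_mapq, verbose = verbose)
  if (is.null(max_mismatch) || is.null(max_gap)) {
    rl <- c(clusters$left$rlen, clusters$right$rlen)
    thr <- if (length(rl)) mismatch_threshold(stats::median(rl)) else 2L
    if (is.null(max_mismatch)) max_mismatch <- thr
    if (is.null(max_gap)) max_gap <- thr
  }
  pairs <- enumerate_pairs(clusters$left, clusters$right,
                           max_span = max_span,
                           min_mapq_pair = min_mapq_pair, layout = layout)
  if (verbose) message("candidate pairs after PEM filter: ", nrow(pairs))

  accepted <- filter_pairs_partitioned(pairs, clusters$left, clusters$right,
                                       scoring, max_mismatch, max_gap,
                                       min_overlap, partitions)
  if (verbose) message("accepted BSJ read pairs: ", nrow(accepted))

  cand <- cluster_junctions(accepted, tolerance = tolerance)
  if (verbose) message("junction clusters: ", nrow(cand))
  out <- apply_final_filters(cand, min_side_support = min_side_support,
                             min_mean_mapq = min_mean_mapq)
  if (verbose) message("candidates after final filters: ", nrow(out))
  if (nrow(out) == 0L && verbose) message("no circRNA candidates survive")
  out
}

filter_pairs_partitioned <- function(pairs, left, right, scoring,
                                     max_mismatch, max_gap, min_overlap,
                                     partitions) {
  partitions <- max(1L, as.integer(partitions))
  if (nrow(pairs) == 0L || partitions == 1L) {
    return(filter_candidate_pairs(pairs, left, right, scoring,
                                  max_mismatch, max_gap, min_overlap))
  }
  chunk <- cut(seq_len(nrow(pairs)), partitions, labels = FALSE)
  parts <- lapply(split(seq_len(nrow(pairs)), chunk), function(ix) {
    filter_candidate_pairs(pairs[ix], left, right, scoring,
                           max_mismatch, max_gap, min_overlap)
  })
  rbindlist(parts)
}

#' Write the circRNA candidate table
#'
#' Writes a TSV with columns `chrom`, `start` (1-based acceptor), `end`
#' (donor), `bsj_count`, `support_left`, `support_right`, `mean_mapq`,
#' `circ_id`; optionally also a BED6 file (0-based half-open, score =
#' BSJ read count).
#'
#' @param candidates Candidate table from [detect_circRNAs()].
#' @param path Output TSV path.
#' @param bed Optional BED6 output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, bed = NULL) {
  tab <- data.table(
    chrom = candidates$chrom,
    start = candidates$acceptor,
    end = candidates$donor,
    bsj_count = candidates$bsj_count,
    support_left = candidates$support_left,
    support_right = candidates$support_right,
    mean_mapq = round(candidates$mean_mapq, 2),
    circ_id = candidates$circ_id)
  fwrite(tab, path, sep = "\t")
  if (!is.null(bed)) {
    bed6 <- data.table(
      chrom = candidates$chrom,
      start = candidates$acceptor - 1L,
      end = candidates$donor,
      name = candidates$circ_id,
      score = candidates$bsj_count,
      strand = ".")
    fwrite(bed6, bed, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read a candidate or truth junction table
#'
#' Reads a TSV with at least `chrom`, `start`, `end` columns (as written
#' by [write_candidates()] or the simulator truth list).
#'
#' @param path TSV path.
#' @return A `data.table`.
#' @export
read_junctions <- function(path) {
  fread(path, sep = "\t")
}
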