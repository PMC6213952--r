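#' Score predicted junctions against a truth set
#'
#' A prediction is a true positive if an as-yet-unmatched truth junction
#' agrees on chromosome with both boundaries within `boundary_tol` bases;
#' matching is greedy one-to-one by smallest total boundary distance.
#' Remaining predictions are false positives; unmatched truths are false
#' negatives. Sensitivity is `TP / (TP + FN)`, precision `TP / (TP + FP)`,
#' and F1 their harmonic mean; undefined ratios (zero denominators) are
#' reported as 0 with a warning.
#'
#' @param predictions,truth Tables with columns `chrom`, `start`, `end`
#'   (1-based inclusive junction boundaries). Candidate tables from
#'   [detect_circRNAs()] (columns `acceptor`/`donor`) are accepted too.
#' @param boundary_tol Maximum per-boundary distance in bases (0 for
#'   simulation truth).
#' @return A list of class `"circ_eval"`: `TP`, `FP`, `FN`, `sensitivity`,
#'   `precision`, `f1`, and `matches` (a `data.table` of matched
#'   prediction/truth row indices).
#' @export
match_predictions <- function(predictions, truth, boundary_tol = 0L) {
  p <- normalize_junctions(predictions)
  t <- normalize_junctions(truth)
  tol <- as.integer(boundary_tol)

  matches <- data.table(p_row = integer(0), t_row = integer(0))
  if (nrow(p) > 0L && nrow(t) > 0L) {
    p[, p_row := .I]
    t[, t_row := .I]
    tw <- t[, .(chrom, slo = start - tol, shi = start + tol,
                elo = end - tol, ehi = end + tol, t_row,
                t_start = start, t_end = end)]
    cand <- p[tw, on = .(chrom, start >= slo, start <= shi,
                         end >= elo, end <= ehi),
              allow.cartesian = TRUE, nomatch = NULL,
              .(p_row = x.p_row, t_row = i.t_row,
                d = abs(x.start - i.t_start) + abs(x.end - i.t_end))]
    setorder(cand, d, p_row, t_row)
    used_p <- logical(nrow(p))
    used_t <- logical(nrow(t))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      pi <- cand$p_row[i]
      ti <- cand$t_row[i]
      if (!used_p[pi] && !used_t[ti]) {
        used_p[pi] <- TRUE
        used_t[ti] <- TRUE
        keep[i] <- TRUE
      }
    }
    matches <- cand[keep, .(p_row, t_row)]
  }

  TP <- nrow(matches)
  FP <- nrow(p) - TP
  FN <- nrow(t) - TP
  res <- list(TP = TP, FP = FP, FN = FN,
              sensitivity = safe_ratio(TP, TP + FN, "sensitivity"),
              precision = safe_ratio(TP, TP + FP, "precision"),
              f1 = NA_real_, matches = matches)
  sp <- res$sensitivity + res$precision
  res$f1 <- if (sp > 0) 2 * res$sensitivity * res$precision / sp else {
    warning("F1 undefined (sensitivity + precision = 0); reporting 0")
    0
  }
  structure(res, class = "circ_eval")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting 0")
    return(0)
  }
  num / den
}

#' @export
print.circ_eval <- function(x, ...) {
  cat(sprintf(
    "TP=%d FP=%d FN=%d  sensitivity=%.4f precision=%.4f F1=%.4f\n",
    x$TP, x$FP, x$FN, x$sensitivity, x$precision, x$f1))
  invisible(x)
}

normalize_junctions <- function(x) {
  x <- as.data.table(x)
  if (!"start" %in% names(x) && "acceptor" %in% names(x)) {
    x <- x[, .(chrom, start = acceptor, end = donor)]
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x[, .(chrom = as.character(chrom), start = as.integer(start),
        end = as.integer(end))]
}

#' RNase R enrichment assessment of candidate circRNAs
#'
#' RNase R degrades linear RNA, so a genuine circRNA should be enriched
#' after treatment. Candidates with fewer than `min_bsj` BSJ reads in the
#' untreated sample are excluded from assessment. Among the rest, a
#' candidate is labeled a true positive iff its treated BSJ read count is
#' at least `min_fold` times its untreated count (inclusive), else a
#' false positive. The false discovery rate is `FP / (TP + FP)`.
#'
#' @param untreated,treated BSJ read counts per candidate: either a named
#'   numeric vector (names are junction ids `chrom:start|end`) or a table
#'   with columns `chrom`, `start`, `end` and `bsj_count` (or `count`).
#' @param min_bsj Basic-filter threshold on the untreated count.
#' @param min_fold Minimum enrichment fold change (inclusive).
#' @param boundary_tol Junction matching tolerance between the two
#'   samples, in bases.
#' @return A list with `labels` (a `data.table`: `circ_id`,
#'   `untreated_count`, `treated_count`, `label` in
#'   `TP`/`FP`/`excluded`) and `fdr`.
#' @export
rnase_r_assess <- function(untreated, treated, min_bsj = 4L, min_fold = 3,
                           boundary_tol = 0L) {
  u <- normalize_counts(untreated)
  t <- normalize_counts(treated)

  ## match treated counts to untreated candidates by junction
  tc <- rep(0, nrow(u))
  if (nrow(u) > 0L && nrow(t) > 0L) {
    m <- match_predictions(u[, .(chrom, start, end)],
                           t[, .(chrom, start, end)],
                           boundary_tol = boundary_tol)
    tc[m$matches$p_row] <- t$count[m$matches$t_row]
  }

  labels <- data.table(
    circ_id = sprintf("%s:%d|%d", u$chrom, u$start, u$end),
    untreated_count = u$count,
    treated_count = tc)
  labels[, label := ifelse(untreated_count < min_bsj, "excluded",
                    ifelse(treated_count >= min_fold * untreated_count,
                           "TP", "FP"))]
  nTP <- sum(labels$label == "TP")
  nFP <- sum(labels$label == "FP")
  fdr <- if (nTP + nFP == 0) {
    warning("no assessable candidates; FDR undefined, reporting 0")
    0
  } else nFP / (nTP + nFP)
  list(labels = labels[], fdr = fdr)
}

normalize_counts <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    parts <- regmatches(names(x),
                        regexec("^(.+):([0-9]+)\\|([0-9]+)$", names(x)))
    bad <- vapply(parts, length, integer(1)) != 4L
    if (any(bad)) stop("unparseable junction id(s): ",
                       paste(names(x)[bad], collapse = ", "))
    return(data.table(
      chrom = vapply(parts, `[`, character(1), 2L),
      start = as.integer(vapply(parts, `[`, character(1), 3L)),
      end = as.integer(vapply(parts, `[`, character(1), 4L)),
      count = as.numeric(x)))
  }
  x <- as.data.table(x)
  if (!"start" %in% names(x) && "acceptor" %in% names(x)) {
    x[, `:=`(start = acceptor, end = donor)]
  }
  cnt <- if ("bsj_count" %in% names(x)) x$bsj_count else x$count
  if (is.null(cnt)) stop("counts must be in a 'bsj_count' or 'count' column")
  data.table(chrom = as.character(x$chrom), start = as.integer(x$start),
             end = as.integer(x$end), count = as.numeric(cnt))
}
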