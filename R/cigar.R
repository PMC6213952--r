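#' Parse a SAM CIGAR string
#'
#' Decomposes a CIGAR string into its ordered run-length operations. The
#' unmapped sentinel `"*"` yields a zero-row result.
#'
#' @param text A single CIGAR string (SAM column 6), e.g. `"30S70M"`.
#' @return A `data.frame` with columns `op` (character, one of
#'   `M I D N S H P = X`) and `length` (integer, >= 1), one row per
#'   operation in order.
#' @examples
#' parse_cigar("30S70M")
#' parse_cigar("*")
#' @export
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (text == "*") {
    return(data.frame(op = character(0), length = integer(0)))
  }
  toks <- regmatches(text, gregexpr("[0-9]+[MIDNSHP=X]", text))[[1]]
  ## the tokens must tile the string exactly, otherwise something is malformed
  if (paste(toks, collapse = "") != text) {
    bad <- sub(paste0("^", paste(toks, collapse = "")), "", text)
    stop("malformed CIGAR '", text, "': unparseable at '", bad, "'")
  }
  op  <- substring(toks, nchar(toks), nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  if (any(len < 1L)) {
    stop("malformed CIGAR '", text, "': zero-length operation")
  }
  data.frame(op = op, length = len)
}

#' Serialise parsed CIGAR operations back to a string
#'
#' Inverse of [parse_cigar()]; a zero-row input yields `"*"`.
#'
#' @param ops A `data.frame` with columns `op` and `length`.
#' @return A single CIGAR string.
#' @export
cigar_string <- function(ops) {
  if (nrow(ops) == 0L) return("*")
  paste0(ops$length, ops$op, collapse = "")
}

#' Classify a clipped alignment into a junction cluster
#'
#' A record clipped at its 5' end in reference orientation (`xS|H yM`) is a
#' potential acceptor-side (left-junction) BSJ record; one clipped at its 3'
#' end (`xM yS|H`) is a potential donor-side (right-junction) record. Records
#' clipped at both ends (three-segment alignments of small circles or short
#' flanking exons) belong to both clusters. Soft (S) and hard (H) clips are
#' treated identically.
#'
#' @param cigar Parsed CIGAR operations as returned by [parse_cigar()].
#' @param min_clip Minimum clip length (bases) for a side to count.
#' @return One of `"LEFT"`, `"RIGHT"`, `"BOTH"`, `"NONE"`.
#' @examples
#' classify_alignment(parse_cigar("30S70M"), min_clip = 10)   # LEFT
#' classify_alignment(parse_cigar("70M30S"), min_clip = 10)   # RIGHT
#' classify_alignment(parse_cigar("20S60M20S"), min_clip = 10) # BOTH
#' @export
classify_alignment <- function(cigar, min_clip = 10L) {
  stopifnot(nrow(cigar) >= 1L)
  clips <- cigar_clips(cigar$op, cigar$length)
  classify_clips(clips[1L], clips[2L], min_clip)
}

## leading/trailing clip lengths (S and H both count, possibly stacked H+S)
cigar_clips <- function(op, len) {
  n <- length(op)
  lead <- 0L
  i <- 1L
  while (i <= n && op[i] %in% c("S", "H")) {
    lead <- lead + len[i]
    i <- i + 1L
  }
  trail <- 0L
  j <- n
  while (j >= i && op[j] %in% c("S", "H")) {
    trail <- trail + len[j]
    j <- j - 1L
  }
  c(lead, trail)
}

classify_clips <- function(lead, trail, min_clip) {
  l <- lead >= min_clip
  r <- trail >= min_clip
  if (l && r) "BOTH" else if (l) "LEFT" else if (r) "RIGHT" else "NONE"
}

## reference span width: M/D/N/=/X consume the reference
cigar_ref_width <- function(op, len) {
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

## read-length contribution: M/I/S/H/=/X (H counts toward the full read)
cigar_read_width <- function(op, len) {
  sum(len[op %in% c("M", "I", "S", "H", "=", "X")])
}
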