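## Independent brute-force oracle for the local aligner: enumerates every
## ungapped diagonal sub-alignment plus every placement of a single gap run
## (first gap column costs gap_open, further columns gap_extend). For short
## sequences and penalty-dominant schemes this attains the optimal local
## score.

oracle_local_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  s <- function(x, y) {
    if (av[x] == bv[y] && av[x] != "N" && bv[y] != "N") match else mismatch
  }
  ## column scores matrix
  SC <- outer(seq_len(n), seq_len(m), Vectorize(s))

  ## best ungapped sub-alignment: enumerate all diagonal subarrays
  best <- 0
  for (d in (-(m - 1)):(n - 1)) {
    xs <- max(1, 1 + d):min(n, m + d)
    v <- SC[cbind(xs, xs - d)]
    cs <- cumsum(c(0, v))
    for (i in seq_along(v)) {
      for (j in i:length(v)) {
        best <- max(best, cs[j + 1] - cs[i])
      }
    }
  }

  ## prefix/suffix best ungapped scores ending/starting at each cell
  P <- matrix(0, n + 2, m + 2) # P[x+1, y+1]: best ending exactly at (x, y)
  for (x in seq_len(n)) {
    for (y in seq_len(m)) {
      P[x + 1, y + 1] <- max(0, P[x, y]) + SC[x, y]
    }
  }
  S <- matrix(0, n + 2, m + 2) # S[x+1, y+1]: best starting exactly at (x, y)
  for (x in n:1) {
    for (y in m:1) {
      S[x + 1, y + 1] <- max(0, S[x + 2, y + 2]) + SC[x, y]
    }
  }

  ## one gap run of length g in b (consumes a[x+1 .. x+g]) or in a
  for (g in seq_len(max(n, m))) {
    pen <- gap_open + (g - 1) * gap_extend
    if (g <= n) {
      for (x in 0:(n - g)) {
        for (y in 0:m) {
          left <- if (x >= 1 && y >= 1) max(0, P[x + 1, y + 1]) else 0
          right <- if (x + g + 1 <= n && y + 1 <= m)
            max(0, S[x + g + 2, y + 2]) else 0
          best <- max(best, left + pen + right)
        }
      }
    }
    if (g <= m) {
      for (y in 0:(m - g)) {
        for (x in 0:n) {
          left <- if (x >= 1 && y >= 1) max(0, P[x + 1, y + 1]) else 0
          right <- if (y + g + 1 <= m && x + 1 <= n)
            max(0, S[x + 2, y + g + 2]) else 0
          best <- max(best, left + pen + right)
        }
      }
    }
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
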