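# Independent reference implementations used to check the package: naive
# substring scans, a brute-force affine-gap DP, and a literal re-statement of
# the left-to-right LEM scan. All are deliberately simple and slow.

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revCompChar <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# all 0-based start positions of pattern in text (overlapping included)
naiveOccurrences <- function(text, pattern) {
  n <- nchar(text); L <- nchar(pattern)
  if (L > n) return(integer(0))
  starts <- seq_len(n - L + 1L)
  which(substring(text, starts, starts + L - 1L) == pattern) - 1L
}

# brute-force affine-gap Smith-Waterman score; gap of length g costs
# open + g * extend; characters outside ACGT (N) never match
affineSWOracle <- function(a, b, match = 1, mismatch = 3, gapOpen = 5,
                           gapExtend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in a (consumes b)
  F <- matrix(NEG, m + 1, n + 1)  # gap in b (consumes a)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gapOpen - gapExtend,
                             E[i + 1, j] - gapExtend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gapOpen - gapExtend,
                             F[i, j + 1] - gapExtend)
      s <- if (av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")) match
           else -mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# literal left-to-right LEM scan: at every read position compute the longest
# exact match against the text by direct substring search, record it iff its
# end exceeds the last recorded end and its length >= Q, and emit all its
# occurrences
naiveLEMScan <- function(read, text, Q) {
  L <- nchar(read); n <- nchar(text)
  windows <- lapply(seq_len(min(L, n)), function(l) {
    starts <- seq_len(n - l + 1L)
    substring(text, starts, starts + l - 1L)
  })
  out <- NULL
  lastEnd <- 0L
  for (p in 0:(L - 1L)) {
    len <- 0L
    while (p + len < L && len < n) {
      cand <- substr(read, p + 1L, p + len + 1L)
      if (grepl("N", cand, fixed = TRUE)) break
      if (!cand %in% windows[[len + 1L]]) break
      len <- len + 1L
    }
    if (len >= Q && p + len > lastEnd) {
      lastEnd <- p + len
      pat <- substr(read, p + 1L, p + len)
      for (g in which(windows[[len]] == pat) - 1L)
        out <- rbind(out, data.frame(readOffset = p, genomePos = g,
                                     length = len))
    }
  }
  if (is.null(out))
    data.frame(readOffset = integer(0), genomePos = integer(0),
               length = integer(0))
  else out[order(out$readOffset, out$genomePos), , drop = FALSE]
}

# recompute an alignment score by walking the traceback CIGAR against the
# sequences (checks score/CIGAR consistency)
cigarScore <- function(tb, read, window, params = alignerParams()) {
  rv <- strsplit(read, "")[[1]]; wv <- strsplit(window, "")[[1]]
  ops <- regmatches(tb$cigar, gregexpr("[0-9]+[MID]", tb$cigar))[[1]]
  i <- tb$readStart; j <- tb$refStart
  score <- 0
  for (op in ops) {
    len <- as.integer(sub("[MID]", "", op))
    type <- sub("[0-9]+", "", op)
    if (type == "M") {
      for (k in seq_len(len)) {
        ok <- rv[i + k] == wv[j + k] && rv[i + k] %in% c("A", "C", "G", "T")
        score <- score + if (ok) params@matchScore else -params@mismatchPenalty
      }
      i <- i + len; j <- j + len
    } else if (type == "I") {
      score <- score - params@gapOpenPenalty - len * params@gapExtendPenalty
      i <- i + len
    } else {
      score <- score - params@gapOpenPenalty - len * params@gapExtendPenalty
      j <- j + len
    }
  }
  score
}
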