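# Seed-size estimation from the binomial error model and MEM seed generation
# via the left-to-right longest-exact-match scan.

#' Estimate the maximal number of errors in a read
#'
#' Under the simplified ungapped error model the number of substitutions
#' \code{w} in a full-length alignment is Binomial(readLen, p); the estimate is
#' the smallest \code{z} with \code{P(w > z) < m} (exact tail, strict
#' inequality).
#'
#' @param readLen read length in bases (>= 1).
#' @param p per-base error probability (default 0.02).
#' @param m missing probability: the allowed chance that a read carries more
#'   than the estimated number of errors (default 0.04).
#' @return Integer error bound \code{e}.
#' @examples
#' estimateMaxErrors(100)  # 5: P(w > 4) = 0.051 >= 0.04 > P(w > 5) = 0.016
#' @export
estimateMaxErrors <- function(readLen, p = 0.02, m = 0.04) {
  readLen <- as.integer(readLen)
  if (is.na(readLen) || readLen < 1L) stop("readLen must be >= 1")
  if (p <= 0) return(0L)
  z <- 0L
  while (stats::pbinom(z, readLen, p, lower.tail = FALSE) >= m) z <- z + 1L
  z
}

#' Estimate the minimal MEM seed size for a read length
#'
#' Pigeonhole bound for non-overlapping q-grams: with at most \code{e} errors
#' (from [estimateMaxErrors()]) at least one of \code{e + 1} non-overlapping
#' q-grams is error-free, so the largest safe seed size is
#' \code{floor(readLen / (e + 1))}, clamped to \code{[qLow, qHigh]}.
#'
#' @param readLen read length in bases (>= 1).
#' @param params an [AlignerParams-class]; \code{errProb}, \code{missProb},
#'   \code{qLow} and \code{qHigh} are used.
#' @return Integer minimal seed size Q.
#' @examples
#' estimateMinSeedSize(100)  # 16
#' estimateMinSeedSize(200)  # 22
#' @export
estimateMinSeedSize <- function(readLen, params = alignerParams()) {
  e <- estimateMaxErrors(readLen, params@errProb, params@missProb)
  q <- as.integer(readLen) %/% (e + 1L)
  max(params@qLow, min(params@qHigh, q))
}

#' Rescue seed size
#'
#' When no MEM of length >= Q exists for a read, the scan is re-run once with
#' the smaller \code{Q_N = floor((Q + qLow) / 2)}.
#'
#' @param Q the minimal seed size in force (>= \code{qLow}).
#' @param qLow the global lower bound (default 13).
#' @return Integer rescue seed size, between \code{qLow} and \code{Q}.
#' @examples
#' rescueSeedSize(22)  # 17
#' @export
rescueSeedSize <- function(Q, qLow = 13L) {
  Q <- as.integer(Q); qLow <- as.integer(qLow)
  if (Q < qLow) stop("Q must be >= qLow")
  (Q + qLow) %/% 2L
}

.emptySeeds <- function() {
  data.frame(readOffset = integer(0), genomePos = integer(0),
             length = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Generate MEM seeds for an oriented read
#'
#' Advances the start position p through the oriented read from left to right,
#' finds the longest exact match (LEM) of the read suffix at each p against
#' the genome, and records it iff it is not contained in the previously
#' recorded LEM (its end must exceed the last recorded end) and its length is
#' at least \code{Q}. Up to \code{h} occurrences per recorded LEM are emitted
#' (smallest suffix-array indices first). Seeds that cross a record boundary
#' or overlap an N position are discarded, as are extensions through read Ns.
#'
#' @param orientedRead the read sequence in alignment orientation (character
#'   or \code{DNAString}); pass the reverse complement for the reverse strand.
#' @param index a [GenomeIndex-class].
#' @param Q minimal seed length (>= 1).
#' @param h maximal occurrences kept per MEM (default 1024).
#' @param strand label stamped on the seeds ("forward" or "reverse").
#' @return A data.frame with columns \code{readOffset}, \code{genomePos}
#'   (both 0-based; \code{genomePos} on the concatenated text), \code{length},
#'   \code{strand}.
#' @export
generateMEMs <- function(orientedRead, index, Q, h = 1024L,
                         strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 1L) stop("Q must be >= 1")
  if (is(orientedRead, "DNAString")) orientedRead <- as.character(orientedRead)
  codes <- cpp_encode(orientedRead)
  if (any(codes < 0L)) stop("read contains a character outside {A,C,G,T,N}")
  if (length(codes) < Q) return(.emptySeeds())
  fm <- index@rev; ssa <- index@revSSA
  mat <- cpp_mem_scan(codes, fm@bwt, fm@dollar, fm@occCheckpoints, fm@u, fm@C,
                      fm@textLength, ssa@marks, ssa@rankBlocks, ssa@values,
                      Q, as.integer(h))
  if (nrow(mat) == 0L) return(.emptySeeds())
  seeds <- data.frame(readOffset = mat[, 1], genomePos = mat[, 2],
                      length = mat[, 3], strand = strand,
                      stringsAsFactors = FALSE)
  ref <- index@reference
  rec <- findInterval(seeds$genomePos, ref@offsets)
  recEnd <- ref@offsets[rec] + ref@seqlengths[rec]
  ok <- seeds$genomePos + seeds$length <= recEnd
  if (any(index@nCumsum > 0)) {
    nOverlap <- index@nCumsum[seeds$genomePos + seeds$length + 1L] -
      index@nCumsum[seeds$genomePos + 1L]
    ok <- ok & nOverlap == 0
  }
  seeds[ok, , drop = FALSE]
}

#' Generate seeds for a read on both strands, with rescue
#'
#' Runs [generateMEMs()] on the read and on its reverse complement with the
#' seed size from [estimateMinSeedSize()]; if no seed is found on either
#' strand, the scan is repeated once with the rescue size from
#' [rescueSeedSize()].
#'
#' @param read read sequence (character or \code{DNAString}).
#' @param index a [GenomeIndex-class].
#' @param params an [AlignerParams-class].
#' @return A list with \code{seeds} (data.frame as in [generateMEMs()], both
#'   strands) and \code{usedQ} (the seed size that produced them).
#' @export
seedsForRead <- function(read, index, params = alignerParams()) {
  if (is(read, "DNAString")) read <- as.character(read)
  rc <- .revComp(read)
  Q <- estimateMinSeedSize(nchar(read), params)
  scan <- function(q) {
    rbind(generateMEMs(read, index, q, params@maxOcc, "forward"),
          generateMEMs(rc, index, q, params@maxOcc, "reverse"))
  }
  seeds <- scan(Q)
  usedQ <- Q
  if (nrow(seeds) == 0L) {
    usedQ <- rescueSeedSize(Q, params@qLow)
    if (usedQ < Q) seeds <- scan(usedQ)
  }
  list(seeds = seeds, usedQ = usedQ)
}

.revComp <- function(s) cpp_revcomp(s)
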