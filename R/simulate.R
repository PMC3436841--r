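# Synthetic data: wgsim-style paired-read simulation with known truth, and
# the recall/precision evaluator.

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' I.i.d. uniform bases, reproducible from the seed; a desk-scale stand-in
#' for a large reference.
#'
#' @param length total genome length in bases (>= 1000).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param nRecords number of equally sized records to split the genome into.
#' @return A [PackedReference-class].
#' @examples
#' simulateGenome(2000, seed = 1)
#' @export
simulateGenome <- function(length, seed = NULL, nRecords = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L) stop("length must be >= 1000")
  nRecords <- as.integer(nRecords)
  codes <- .withSeed(seed, sample.int(4L, length, replace = TRUE) - 1L)
  per <- diff(round(seq(0, length, length.out = nRecords + 1L)))
  new("PackedReference",
      seqnames = paste0("sim", seq_len(nRecords)),
      seqlengths = as.integer(per),
      offsets = c(0L, cumsum(as.integer(per)))[seq_len(nRecords)],
      codes = codes)
}

# apply the uniform error process to template codes and cut a read of exactly
# L bases: each base errs with probability errorRate; an error is a
# substitution with probability 1 - indelFraction, else a 1-base insertion or
# deletion with equal probability
.corruptTemplate <- function(tmpl, L, errorRate, indelFraction) {
  n <- length(tmpl)
  if (errorRate <= 0) return(tmpl[seq_len(L)])
  r <- stats::runif(n)
  u <- stats::runif(n)
  type <- integer(n)                                 # 0 none, 1 sub, 2 ins, 3 del
  isErr <- r < errorRate
  type[isErr & u < (1 - indelFraction)] <- 1L
  type[isErr & u >= (1 - indelFraction) & u < (1 - indelFraction / 2)] <- 2L
  type[isErr & u >= (1 - indelFraction / 2)] <- 3L
  v <- tmpl
  sub <- type == 1L
  if (any(sub))
    v[sub] <- (tmpl[sub] + sample.int(3L, sum(sub), replace = TRUE)) %% 4L
  counts <- c(1L, 1L, 2L, 0L)[type + 1L]
  idx <- rep.int(seq_len(n), counts)
  out <- v[idx]
  ins <- which(type == 2L)
  if (length(ins))                                   # random base precedes the kept base
    out[cumsum(counts)[ins] - 1L] <- sample.int(4L, length(ins),
                                                replace = TRUE) - 1L
  if (length(out) < L)                               # pathological deletion pile-up
    out <- c(out, sample.int(4L, L - length(out), replace = TRUE) - 1L)
  out[seq_len(L)]
}

#' Simulate paired-end reads with known truth
#'
#' wgsim-style simulation: fragment start uniform on a record, fragment length
#' normal (rounded, clamped to at least twice the read length), mate 1 read
#' from the fragment's left end on the forward strand, mate 2 the reverse
#' complement of its right end. Each base is independently errored with
#' probability \code{errorRate}; an error is a substitution with probability
#' \code{1 - indelFraction}, otherwise a 1-base insertion or deletion with
#' equal probability. Truth records the pre-error origin (0-based leftmost
#' forward-strand coordinate).
#'
#' @param genome a [PackedReference-class] (e.g. from [simulateGenome()]).
#' @param numPairs number of read pairs.
#' @param readLength read length in bases.
#' @param errorRate uniform per-base error probability in \code{[0, 0.5)}.
#' @param indelFraction fraction of errors that are indels (default 0.10).
#' @param insertMean,insertSd insert-size (outer fragment length) normal
#'   model; \code{insertMean} must be at least \code{2 * readLength}.
#' @param seed RNG seed.
#' @return A list with \code{reads1}, \code{reads2} (character vectors),
#'   \code{names} (one per pair) and \code{truth}: a data.frame with one row
#'   per read (\code{name} suffixed \code{/1}, \code{/2}; \code{record};
#'   \code{pos}; \code{strand}).
#' @export
simulatePairs <- function(genome, numPairs, readLength = 200L,
                          errorRate = 0.02, indelFraction = 0.10,
                          insertMean = 1000, insertSd = 50, seed = NULL) {
  stopifnot(is(genome, "PackedReference"))
  numPairs <- as.integer(numPairs)
  readLength <- as.integer(readLength)
  if (numPairs < 1L || readLength < 1L) stop("counts must be positive")
  if (errorRate < 0 || errorRate >= 0.5) stop("errorRate must be in [0, 0.5)")
  if (insertMean < 2 * readLength)
    stop("insertMean must be at least twice the read length")
  .withSeed(seed, {
    pad <- min(readLength,
               16L + ceiling(4 * readLength * errorRate * indelFraction))
    recLens <- genome@seqlengths
    recProb <- recLens / sum(recLens)
    reads1 <- character(numPairs); reads2 <- character(numPairs)
    rec <- integer(numPairs); pos1 <- integer(numPairs); pos2 <- integer(numPairs)
    for (i in seq_len(numPairs)) {
      repeat {
        ri <- sample.int(length(recLens), 1L, prob = recProb)
        frag <- max(2L * readLength,
                    as.integer(round(stats::rnorm(1, insertMean, insertSd))))
        if (frag + pad >= recLens[ri]) next   # fragment cannot fit: resample
        start <- sample.int(recLens[ri] - frag - pad + 1L, 1L) - 1L
        break
      }
      off <- genome@offsets[ri]
      g1 <- off + start
      g2 <- off + start + frag - readLength
      # both mates are corrupted anchored at their leftmost genome
      # coordinate (the truth coordinate), mate 2 in forward-strand space and
      # then reverse-complemented: the error process is orientation-blind, and
      # this keeps truth exact under indels, as wgsim's haplotype-space indels
      t1 <- genome@codes[(g1 + 1L):(g1 + readLength + pad)]
      t2 <- genome@codes[(g2 + 1L):(g2 + readLength + pad)]
      r2 <- .corruptTemplate(t2, readLength, errorRate, indelFraction)
      reads1[i] <- cpp_decode(.corruptTemplate(t1, readLength, errorRate,
                                               indelFraction))
      reads2[i] <- cpp_decode(rev(ifelse(r2 == 4L, 4L, 3L - r2)))
      rec[i] <- ri; pos1[i] <- start; pos2[i] <- start + frag - readLength
    }
    nm <- sprintf("sim%06d", seq_len(numPairs))
    truth <- data.frame(
      name = c(paste0(nm, "/1"), paste0(nm, "/2")),
      record = genome@seqnames[c(rec, rec)],
      pos = c(pos1, pos2),
      strand = rep(c("forward", "reverse"), each = numPairs),
      stringsAsFactors = FALSE)
    list(reads1 = reads1, reads2 = reads2, names = nm, truth = truth)
  })
}

.leadingClip <- function(cigar) {
  m <- regexpr("^[0-9]+S", cigar)
  out <- integer(length(cigar))
  has <- m > 0L
  out[has] <- as.integer(sub("S$", "", regmatches(cigar, m)))
  out
}

#' Evaluate alignments against simulation truth
#'
#' A read is correctly aligned when it maps to the true record and strand with
#' a reported position within \code{maxDist} of the truth. The reported
#' position is the unclipped leftmost coordinate (SAM POS minus the leading
#' soft clip): local alignment clips error-bearing read ends, which shifts POS
#' although the placement is correct, and truth refers to the full-read
#' origin. Recall divides correct reads by all reads in \code{truth};
#' precision divides by the aligned reads that pass \code{minMapq}.
#'
#' @param results data.frame of alignment rows (from [alignReads()]) or the
#'   path to a SAM file written by [writeSAM()].
#' @param truth truth data.frame as from [simulatePairs()].
#' @param maxDist maximal distance to the true position (default 5; use 0 for
#'   the exact-position high-mapq analysis).
#' @param minMapq only alignments with \code{mapq >= minMapq} count as
#'   aligned (default 0).
#' @return A list with \code{recall}, \code{precision}, \code{nAligned},
#'   \code{nCorrect}, \code{nTotal} and \code{degenerate} (TRUE when nothing
#'   aligned, in which case precision is reported as 0).
#' @export
evaluateAlignments <- function(results, truth, maxDist = 5L, minMapq = 0L) {
  if (is.character(results)) results <- .readSamFile(results)
  key <- results$qname
  pe <- bitwAnd(results$flag, 1L) != 0L
  key[pe & bitwAnd(results$flag, 64L) != 0L] <-
    paste0(key[pe & bitwAnd(results$flag, 64L) != 0L], "/1")
  key[pe & bitwAnd(results$flag, 128L) != 0L] <-
    paste0(key[pe & bitwAnd(results$flag, 128L) != 0L], "/2")
  hit <- match(key, truth$name)
  if (anyNA(hit)) stop("read name absent from truth: ", key[which(is.na(hit))[1]])
  aligned <- bitwAnd(results$flag, 4L) == 0L & results$mapq >= minMapq
  reported <- results$pos - 1L - .leadingClip(results$cigar)
  strand <- ifelse(bitwAnd(results$flag, 16L) != 0L, "reverse", "forward")
  correct <- aligned &
    results$rname == truth$record[hit] &
    strand == truth$strand[hit] &
    abs(reported - truth$pos[hit]) <= maxDist
  nAligned <- sum(aligned)
  nCorrect <- sum(correct)
  nTotal <- nrow(truth)
  list(recall = nCorrect / nTotal,
       precision = if (nAligned > 0) nCorrect / nAligned else 0,
       nAligned = nAligned, nCorrect = nCorrect, nTotal = nTotal,
       degenerate = nAligned == 0L)
}

# minimal SAM body reader for the evaluator / CLI round trip
.readSamFile <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0)))
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[`, "", 1L),
             flag = as.integer(vapply(f, `[`, "", 2L)),
             rname = vapply(f, `[`, "", 3L),
             pos = as.integer(vapply(f, `[`, "", 4L)),
             mapq = as.integer(vapply(f, `[`, "", 5L)),
             cigar = vapply(f, `[`, "", 6L),
             stringsAsFactors = FALSE)
}
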