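# Paired-end mapping: seed pairing under strand / insert-size constraints,
# pair finalization, and mate rescue by windowed alignment.

#' Estimate the ungapped mapping position of a read from one of its seeds
#'
#' Assuming the read aligns without gaps, its leftmost genome coordinate is
#' the seed's genome position minus its offset in the oriented read.
#'
#' @param seed a seed data.frame (rows as from [generateMEMs()]); vectorized.
#' @param readLen read length (accepted for interface symmetry; the leftmost
#'   estimate does not depend on it).
#' @return Integer vector of estimated 0-based leftmost positions.
#' @examples
#' estimateMappingPosition(data.frame(readOffset = 20, genomePos = 1000))  # 980
#' @export
estimateMappingPosition <- function(seed, readLen = NULL) {
  as.integer(seed$genomePos - seed$readOffset)
}

.maxMappingDistance <- function(params) params@insertMean +
  params@insertK * params@insertSd

#' Pair seeds of two mates under strand and distance constraints
#'
#' Enumerates seed pairs, keeping those on opposite strands and the same
#' reference record, in forward/reverse orientation, whose estimated ungapped
#' outer distance does not exceed the maximal mapping distance
#' (\code{insertMean + insertK * insertSd}) plus a slack of
#' \code{indelSlack(len1) + indelSlack(len2)} compensating for the gap-blind
#' position estimate. Qualified pairs are ordered by combined seed length,
#' descending.
#'
#' @param seeds1,seeds2 seed data.frames for the two mates.
#' @param readLen1,readLen2 mate read lengths.
#' @param params an [AlignerParams-class].
#' @param index a [GenomeIndex-class] (record lookup).
#' @return data.frame with \code{idx1}, \code{idx2} (row indices into the
#'   seed frames), \code{dist} (estimated outer distance) and \code{combLen}.
#' @export
pairSeeds <- function(seeds1, seeds2, readLen1, readLen2,
                      params = alignerParams(), index) {
  empty <- data.frame(idx1 = integer(0), idx2 = integer(0),
                      dist = integer(0), combLen = integer(0))
  if (nrow(seeds1) == 0L || nrow(seeds2) == 0L) return(empty)
  # keep the enumeration tractable on repetitive inputs
  cap <- 512L
  take <- function(s) {
    if (nrow(s) > cap) s[order(-s$length)[seq_len(cap)], , drop = FALSE] else s
  }
  s1 <- take(seeds1); s2 <- take(seeds2)
  ref <- index@reference
  ts1 <- estimateMappingPosition(s1); ts2 <- estimateMappingPosition(s2)
  rec1 <- .seedRecord(ref, s1$genomePos); rec2 <- .seedRecord(ref, s2$genomePos)
  i <- rep(seq_len(nrow(s1)), times = nrow(s2))
  j <- rep(seq_len(nrow(s2)), each = nrow(s1))
  keep <- s1$strand[i] != s2$strand[j] & rec1[i] == rec2[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)
  fwdTs <- ifelse(s1$strand[i] == "forward", ts1[i], ts2[j])
  revTs <- ifelse(s1$strand[i] == "forward", ts2[j], ts1[i])
  left <- pmin(ts1[i], ts2[j])
  right <- pmax(ts1[i] + readLen1, ts2[j] + readLen2)
  d <- right - left
  slack <- indelSlack(readLen1, params) + indelSlack(readLen2, params)
  keep2 <- fwdTs <= revTs & d <= .maxMappingDistance(params) + slack
  i <- i[keep2]; j <- j[keep2]; d <- d[keep2]
  if (length(i) == 0L) return(empty)
  out <- data.frame(idx1 = match(rownames(s1)[i], rownames(seeds1)),
                    idx2 = match(rownames(s2)[j], rownames(seeds2)),
                    dist = as.integer(d),
                    combLen = s1$length[i] + s2$length[j])
  out[order(-out$combLen, out$dist), , drop = FALSE]
}

# shared acceptance test for one traceback
.passesFilters <- function(tb, params) {
  !is.null(tb) && tb$identity >= params@minIdentity &&
    tb$coverage >= params@minCoverage
}

.outerDistance <- function(g1, e1, g2, e2) max(e1, e2) - min(g1, g2)

#' Finalize a read pair from qualified seed pairs
#'
#' Walks the qualified seed pairs in order, aligns both mates in the windows
#' implied by the paired seeds, and accepts the first pair whose alignments
#' pass the identity/coverage filters and whose true outer distance respects
#' the insert-size constraint.
#'
#' @param candidates data.frame from [pairSeeds()].
#' @param cand1,cand2 per-mate candidate state as built by the single-end
#'   stage (internal lists carrying seeds, oriented codes and ranked regions).
#' @param index a [GenomeIndex-class].
#' @param params an [AlignerParams-class].
#' @param maxCandidates number of seed pairs to try before giving up.
#' @return \code{NULL}, or a list with tracebacks \code{tb1}, \code{tb2} and
#'   strands \code{strand1}, \code{strand2}.
#' @keywords internal
finalizePair <- function(candidates, cand1, cand2, index, params,
                         maxCandidates = 64L) {
  maxDist <- .maxMappingDistance(params)
  n <- min(nrow(candidates), maxCandidates)
  for (k in seq_len(n)) {
    s1 <- cand1$seeds[candidates$idx1[k], ]
    s2 <- cand2$seeds[candidates$idx2[k], ]
    r1 <- determineRegion(s1, cand1$readLen, params, index)
    r2 <- determineRegion(s2, cand2$readLen, params, index)
    tb1 <- .tracebackRegion(cand1$orient[[s1$strand]], index, r1$start, r1$end,
                            params)
    if (!.passesFilters(tb1, params)) next
    tb2 <- .tracebackRegion(cand2$orient[[s2$strand]], index, r2$start, r2$end,
                            params)
    if (!.passesFilters(tb2, params)) next
    if (.outerDistance(tb1$gpos, tb1$gend, tb2$gpos, tb2$gend) > maxDist) next
    return(list(tb1 = tb1, tb2 = tb2, strand1 = s1$strand, strand2 = s2$strand))
  }
  NULL
}

#' Rescue an unaligned or discordant mate through its aligned anchor
#'
#' The insert-size model confines the mate to a genomic window around the
#' anchor: outer distances in \code{[insertMean - k sd, insertMean + k sd]}
#' place the mate downstream of a forward anchor (as reverse complement) or
#' upstream of a reverse anchor. The mate is aligned by Smith-Waterman inside
#' that window (clamped to the record) and accepted under the usual filters;
#' its mapping quality is \code{floor(r * mateMapq)}.
#'
#' @param anchor a one-row aligned data.frame (as from [alignReadSE()]) that
#'   passed the filters.
#' @param mateRead the mate's sequence (character).
#' @param index a [GenomeIndex-class].
#' @param params an [AlignerParams-class].
#' @param mateName name for the rescued record.
#' @param qual optional quality string of the mate.
#' @return A one-row alignment data.frame, or \code{NULL} when the window is
#'   empty or the filters fail.
#' @export
rescueMate <- function(anchor, mateRead, index, params = alignerParams(),
                       mateName = "mate", qual = NULL) {
  ref <- index@reference
  L <- nchar(mateRead)
  slack <- indelSlack(L, params)
  dmin <- max(0, params@insertMean - params@insertK * params@insertSd)
  dmax <- params@insertMean + params@insertK * params@insertSd
  anchorRev <- bitwAnd(anchor$flag, 16L) != 0L
  if (!anchorRev) {
    wstart <- anchor$gpos + dmin - L - slack
    wend <- anchor$gpos + dmax
    mateStrand <- "reverse"
  } else {
    wstart <- anchor$gend - dmax
    wend <- anchor$gend - dmin + L + slack
    mateStrand <- "forward"
  }
  rec <- .toRecordCoords(ref, anchor$gpos)$rec
  recStart <- ref@offsets[rec]
  recEnd <- recStart + ref@seqlengths[rec]
  wstart <- as.integer(max(recStart, floor(wstart)))
  wend <- as.integer(min(recEnd, ceiling(wend)))
  if (wend - wstart < min(L, params@minScore)) return(NULL)
  orient <- if (mateStrand == "reverse") cpp_encode(.revComp(mateRead))
            else cpp_encode(mateRead)
  tb <- .tracebackRegion(orient, index, wstart, wend, params)
  if (!.passesFilters(tb, params)) return(NULL)
  mq <- mapqPE("rescued", mateSeMapq = anchor$mapq, r = tb$coverage)
  .alignmentRow(mateName, orient, tb, mateStrand, mq, index, qual)
}

# set PE flags / RNEXT / PNEXT / TLEN on the two records
.applyPairFlags <- function(a1, a2, proper) {
  base1 <- 1L + 64L; base2 <- 1L + 128L
  m1 <- bitwAnd(a1$flag, 4L) != 0L  # self unmapped
  m2 <- bitwAnd(a2$flag, 4L) != 0L
  r1 <- bitwAnd(a1$flag, 16L) != 0L
  r2 <- bitwAnd(a2$flag, 16L) != 0L
  f1 <- base1 + (if (m1) 4L else 0L) + (if (m2) 8L else 0L) +
    (if (r1) 16L else 0L) + (if (!m2 && r2) 32L else 0L) +
    (if (proper) 2L else 0L)
  f2 <- base2 + (if (m2) 4L else 0L) + (if (m1) 8L else 0L) +
    (if (r2) 16L else 0L) + (if (!m1 && r1) 32L else 0L) +
    (if (proper) 2L else 0L)
  a1$flag <- f1; a2$flag <- f2
  if (!m1 && !m2) {
    same <- a1$rname == a2$rname
    a1$rnext <- if (same) "=" else a2$rname
    a2$rnext <- if (same) "=" else a1$rname
    a1$pnext <- a2$pos; a2$pnext <- a1$pos
    if (same) {
      outer <- .outerDistance(a1$gpos, a1$gend, a2$gpos, a2$gend)
      first1 <- a1$gpos < a2$gpos || (a1$gpos == a2$gpos && TRUE)
      a1$tlen <- if (first1) outer else -outer
      a2$tlen <- -a1$tlen
    }
  } else if (!m1) {
    a2$rnext <- a1$rname; a2$pnext <- a1$pos
  } else if (!m2) {
    a1$rnext <- a2$rname; a1$pnext <- a2$pos
  }
  list(a1, a2)
}

#' Align a read pair (paired-end)
#'
#' Full paired-end pipeline: single-end candidate generation for both mates;
#' acceptance of the independently best alignments when they already satisfy
#' the strand and insert-size constraints (\code{distance_ok}); otherwise seed
#' pairing and windowed finalization (\code{seed_paired}); otherwise rescue of
#' the missing or discordant mate through its anchor (\code{rescued}); and
#' finally SAM-ready records with pair flags and TLEN. Rescue never overrides
#' an existing concordant pairing.
#'
#' @param read1,read2 mate sequences (character or \code{DNAString}).
#' @param index a [GenomeIndex-class].
#' @param params an [AlignerParams-class]; \code{insertMean},
#'   \code{insertSd}, \code{insertK} define the distance constraint.
#' @param name template name for both records.
#' @param qual1,qual2 optional quality strings.
#' @return A list with \code{aln1}, \code{aln2} (one-row data.frames),
#'   \code{pairing} (\code{"seed_paired"}, \code{"distance_ok"},
#'   \code{"rescued"} or \code{"unpaired"}) and \code{tlen} (signed template
#'   length of the first mate, 0 when not paired).
#' @export
alignPair <- function(read1, read2, index, params = alignerParams(),
                      name = "pair", qual1 = NULL, qual2 = NULL) {
  if (is(read1, "DNAString")) read1 <- as.character(read1)
  if (is(read2, "DNAString")) read2 <- as.character(read2)
  cand1 <- .seCandidates(read1, index, params, name)
  cand2 <- .seCandidates(read2, index, params, name)
  se1 <- .finishSE(cand1, index, params, qual1)
  se2 <- .finishSE(cand2, index, params, qual2)
  maxDist <- .maxMappingDistance(params)
  aln1 <- NULL; aln2 <- NULL; pairing <- "unpaired"

  concordant <- function(a, b) {
    !is.null(a) && !is.null(b) &&
      bitwAnd(a$flag, 16L) != bitwAnd(b$flag, 16L) &&
      a$rname == b$rname &&
      .outerDistance(a$gpos, a$gend, b$gpos, b$gend) <= maxDist
  }

  if (concordant(se1, se2)) {
    aln1 <- se1; aln2 <- se2; pairing <- "distance_ok"
  } else {
    cands <- pairSeeds(cand1$seeds, cand2$seeds, cand1$readLen, cand2$readLen,
                       params, index)
    fp <- finalizePair(cands, cand1, cand2, index, params)
    if (!is.null(fp)) {
      mq1 <- .pairSeMapq(cand1, fp$tb1)
      mq2 <- .pairSeMapq(cand2, fp$tb2)
      aln1 <- .alignmentRow(name, cand1$orient[[fp$strand1]], fp$tb1,
                            fp$strand1, mq1, index, qual1)
      aln2 <- .alignmentRow(name, cand2$orient[[fp$strand2]], fp$tb2,
                            fp$strand2, mq2, index, qual2)
      pairing <- "seed_paired"
    } else if (!is.null(se1) || !is.null(se2)) {
      # rescue through the better-supported anchor
      anchor1 <- if (is.null(se2)) TRUE
                 else if (is.null(se1)) FALSE
                 else se1$mapq >= se2$mapq
      anchor <- if (anchor1) se1 else se2
      mate <- if (anchor1) read2 else read1
      mq <- if (anchor1) qual2 else qual1
      res <- rescueMate(anchor, mate, index, params, name, mq)
      if (!is.null(res) &&
          .outerDistance(anchor$gpos, anchor$gend, res$gpos, res$gend) <=
            maxDist) {
        if (anchor1) { aln1 <- se1; aln2 <- res } else { aln1 <- res; aln2 <- se2 }
        pairing <- "rescued"
      }
    }
  }

  if (pairing == "unpaired") {
    aln1 <- if (is.null(se1)) .unalignedRow(name, read1, qual1) else se1
    aln2 <- if (is.null(se2)) .unalignedRow(name, read2, qual2) else se2
  }
  out <- .applyPairFlags(aln1, aln2, proper = pairing != "unpaired")
  list(aln1 = out[[1]], aln2 = out[[2]], pairing = pairing,
       tlen = out[[1]]$tlen)
}

# SE-style mapping quality for a seed-paired mate: best/second-best from its
# ranked list (falling back to the pair alignment's own score)
.pairSeMapq <- function(cand, tb) {
  ranked <- cand$ranked
  b1 <- if (nrow(ranked) >= 1L) max(ranked$score[1], tb$score) else tb$score
  b2 <- if (nrow(ranked) >= 2L) min(ranked$score[2], b1) else 0L
  mapqSE(b1, b2, tb$coverage)
}
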