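# Seed extension: mapping-region determination, affine-gap local alignment
# (score and traceback), region ranking and the single-end alignment pipeline.

#' Indel slack for region determination
#'
#' The largest total gap length an alignment scoring at least \code{minScore}
#' can contain: each aligned base contributes at most \code{matchScore}, so the
#' score budget available for gaps is \code{readLen * matchScore - minScore -
#' gapOpenPenalty}, paid at \code{gapExtendPenalty} per gapped base. The result
#' is additionally capped at \code{2 * readLen}, the maximal extension that is
#' always safe because a positive-score local alignment cannot span more than
#' twice the read length under a scoring scheme whose penalties exceed the
#' match score.
#'
#' @param readLen read length in bases (>= 1).
#' @param params an [AlignerParams-class].
#' @return Integer slack in bases (0 when the score budget is exhausted).
#' @examples
#' indelSlack(100)  # 32
#' @export
indelSlack <- function(readLen, params = alignerParams()) {
  readLen <- as.integer(readLen)
  budget <- readLen * params@matchScore - params@minScore - params@gapOpenPenalty
  if (budget <= 0L) return(0L)
  min(budget %/% params@gapExtendPenalty, 2L * readLen)
}

.seedRecord <- function(ref, genomePos) findInterval(genomePos, ref@offsets)

#' Determine the mapping region implied by a seed
#'
#' Assuming the MEM is part of the final alignment, the read extends at most
#' \code{readOffset} bases left of the seed and \code{readLen - readOffset -
#' length} bases right of it, plus [indelSlack()] bases of gap allowance on
#' each side. The window is clamped to the seed's reference record.
#'
#' @param seed a one-row data.frame (or list) with \code{readOffset},
#'   \code{genomePos}, \code{length}, \code{strand} as from [generateMEMs()].
#' @param readLen length of the read.
#' @param params an [AlignerParams-class].
#' @param index a [GenomeIndex-class] (or [PackedReference-class]) supplying
#'   record bounds.
#' @return A one-row data.frame with \code{start}, \code{end} (0-based
#'   half-open on the concatenated genome) and \code{strand}.
#' @export
determineRegion <- function(seed, readLen, params, index) {
  ref <- if (is(index, "GenomeIndex")) index@reference else index
  slack <- indelSlack(readLen, params)
  rec <- .seedRecord(ref, seed$genomePos)
  recStart <- ref@offsets[rec]
  recEnd <- recStart + ref@seqlengths[rec]
  start <- pmax(recStart, seed$genomePos - seed$readOffset - slack)
  end <- pmin(recEnd,
              seed$genomePos + seed$length +
                (readLen - seed$readOffset - seed$length) + slack)
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = seed$strand, stringsAsFactors = FALSE)
}

#' Merge overlapping mapping regions
#'
#' Windows on the same strand whose half-open intervals overlap are unioned so
#' that each merged window is aligned once; seed bookkeeping is concatenated.
#' Abutting but non-overlapping windows (e.g. across a record boundary) are
#' kept apart.
#'
#' @param regions data.frame with \code{start}, \code{end}, \code{strand} and
#'   optionally \code{seedIdx} (list column or integer).
#' @return data.frame of merged regions with a \code{seedIdx} list column.
#' @export
mergeRegions <- function(regions) {
  if (nrow(regions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  if (is.null(regions$seedIdx)) regions$seedIdx <- seq_len(nrow(regions))
  out <- lapply(split(regions, regions$strand), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red),
               strand = d$strand[1],
               seedIdx = I(lapply(revmap, function(i) unlist(d$seedIdx[i]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.readCodes <- function(read) {
  if (is(read, "DNAString")) read <- as.character(read)
  if (is.character(read)) {
    codes <- cpp_encode(read)
    if (any(codes < 0L)) stop("sequence contains a character outside {A,C,G,T,N}")
    codes
  } else as.integer(read)
}

#' Optimal local alignment score (affine gaps)
#'
#' Smith-Waterman score under affine gap costs: a gap of length g costs
#' \code{gapOpenPenalty + g * gapExtendPenalty}. N never matches.
#'
#' @param read,refWindow sequences (character, \code{DNAString}, or integer
#'   base codes).
#' @param params an [AlignerParams-class] holding the scoring scheme.
#' @return Integer score (0 when no positive-scoring alignment exists).
#' @examples
#' localAlignScore("ACGT", "ACGT")  # 4
#' @export
localAlignScore <- function(read, refWindow, params = alignerParams()) {
  cpp_sw_score(.readCodes(read), .readCodes(refWindow),
               params@matchScore, params@mismatchPenalty,
               params@gapOpenPenalty, params@gapExtendPenalty)
}

#' Local alignment with traceback
#'
#' Like [localAlignScore()] but also reports the alignment path: a CIGAR over
#' the window (soft clips added for unaligned read ends), the 0-based offsets
#' of the aligned read and window spans, percentage identity (matches /
#' aligned columns) and read coverage (aligned read bases / read length).
#'
#' @inheritParams localAlignScore
#' @return \code{NULL} when the best score is 0; otherwise a list with
#'   \code{score}, \code{cigar}, \code{readStart}, \code{readEnd},
#'   \code{refStart}, \code{refEnd} (half-open, window coordinates),
#'   \code{identity}, \code{coverage}, \code{nMatch}, \code{nMismatch},
#'   \code{nIns}, \code{nDel}.
#' @export
localAlignTraceback <- function(read, refWindow, params = alignerParams()) {
  rc <- .readCodes(read)
  tb <- cpp_sw_traceback(rc, .readCodes(refWindow),
                         params@matchScore, params@mismatchPenalty,
                         params@gapOpenPenalty, params@gapExtendPenalty)
  if (tb$score <= 0) return(NULL)
  L <- length(rc)
  leadS <- tb$readStart
  trailS <- L - tb$readEnd
  cigar <- paste0(if (leadS > 0L) paste0(leadS, "S") else "",
                  tb$cigar,
                  if (trailS > 0L) paste0(trailS, "S") else "")
  cols <- tb$nMatch + tb$nMismatch + tb$nIns + tb$nDel
  refSpan <- tb$refEnd - tb$refStart
  stopifnot(refSpan <= 2L * L)  # positive-score alignments cannot span > 2|S|
  list(score = tb$score, cigar = cigar,
       readStart = tb$readStart, readEnd = tb$readEnd,
       refStart = tb$refStart, refEnd = tb$refEnd,
       identity = tb$nMatch / cols,
       coverage = (tb$readEnd - tb$readStart) / L,
       nMatch = tb$nMatch, nMismatch = tb$nMismatch,
       nIns = tb$nIns, nDel = tb$nDel)
}

#' Rank mapping regions by alignment score
#'
#' Regions scoring below \code{minScore} are removed; the rest are sorted by
#' descending score, ties broken by ascending start then strand for
#' determinism.
#'
#' @param regions data.frame with at least \code{score}, \code{start},
#'   \code{strand}.
#' @param params an [AlignerParams-class] (for \code{minScore}).
#' @return The filtered, sorted data.frame.
#' @export
rankRegions <- function(regions, params = alignerParams()) {
  if (nrow(regions) == 0L) return(regions)
  keep <- regions$score >= params@minScore
  regions <- regions[keep, , drop = FALSE]
  regions[order(-regions$score, regions$start, regions$strand), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# internal single-end machinery shared with the paired-end pipeline

.windowCodes <- function(ref, start, end) ref@codes[(start + 1L):end]

.toRecordCoords <- function(ref, gpos) {
  rec <- findInterval(gpos, ref@offsets)
  list(rname = ref@seqnames[rec], pos0 = gpos - ref@offsets[rec], rec = rec)
}

# traceback of an oriented read inside [start, end) of the concatenated genome
.tracebackRegion <- function(orientedCodes, index, start, end, params) {
  tb <- localAlignTraceback(orientedCodes,
                            .windowCodes(index@reference, start, end), params)
  if (is.null(tb)) return(NULL)
  tb$gpos <- start + tb$refStart
  tb$gend <- start + tb$refEnd
  tb
}

# seeds -> merged scored regions, ranked
.seCandidates <- function(read, index, params, name = "read") {
  if (is(read, "DNAString")) read <- as.character(read)
  L <- nchar(read)
  sfr <- seedsForRead(read, index, params)
  seeds <- sfr$seeds
  orient <- list(forward = cpp_encode(read),
                 reverse = cpp_encode(.revComp(read)))
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = integer(0))
  if (nrow(seeds) == 0L) {
    return(list(name = name, read = read, readLen = L, orient = orient,
                seeds = seeds, usedQ = sfr$usedQ, ranked = empty))
  }
  regions <- determineRegion(seeds, L, params, index)
  regions$seedIdx <- seq_len(nrow(seeds))
  merged <- mergeRegions(regions)
  merged$score <- vapply(seq_len(nrow(merged)), function(i) {
    cpp_sw_score(orient[[merged$strand[i]]],
                 .windowCodes(index@reference, merged$start[i], merged$end[i]),
                 params@matchScore, params@mismatchPenalty,
                 params@gapOpenPenalty, params@gapExtendPenalty)
  }, integer(1))
  list(name = name, read = read, readLen = L, orient = orient, seeds = seeds,
       usedQ = sfr$usedQ, ranked = rankRegions(merged, params))
}

.samColumns <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
                 "pnext", "tlen", "seq", "qual", "score", "nm", "identity",
                 "coverage", "gpos", "gend")

.unalignedRow <- function(name, seq, qual = NULL, flag = 4L) {
  data.frame(qname = name, flag = flag, rname = "*", pos = 0L, mapq = 0L,
             cigar = "*", rnext = "*", pnext = 0L, tlen = 0L, seq = seq,
             qual = if (is.null(qual)) "*" else qual, score = NA_integer_,
             nm = NA_integer_, identity = NA_real_, coverage = NA_real_,
             gpos = NA_integer_, gend = NA_integer_, stringsAsFactors = FALSE)
}

.alignmentRow <- function(name, orientCodes, tb, strand, mapq, index,
                          qual = NULL) {
  ref <- index@reference
  rc <- .toRecordCoords(ref, tb$gpos)
  seq <- cpp_decode(orientCodes)
  q <- if (is.null(qual)) "*"
       else if (strand == "reverse") paste(rev(strsplit(qual, "")[[1]]),
                                           collapse = "")
       else qual
  data.frame(qname = name, flag = if (strand == "reverse") 16L else 0L,
             rname = rc$rname, pos = rc$pos0 + 1L,
             mapq = as.integer(mapq), cigar = tb$cigar, rnext = "*",
             pnext = 0L, tlen = 0L, seq = seq, qual = q,
             score = as.integer(tb$score),
             nm = as.integer(tb$nMismatch + tb$nIns + tb$nDel),
             identity = tb$identity, coverage = tb$coverage,
             gpos = as.integer(tb$gpos), gend = as.integer(tb$gend),
             stringsAsFactors = FALSE)
}

# traceback + filters + mapq for the best ranked region; NULL when the read
# cannot be reported
.finishSE <- function(cand, index, params, qual = NULL) {
  ranked <- cand$ranked
  if (nrow(ranked) == 0L) return(NULL)
  b1 <- ranked$score[1]
  b2 <- if (nrow(ranked) >= 2L) ranked$score[2] else 0L
  tb <- .tracebackRegion(cand$orient[[ranked$strand[1]]], index,
                         ranked$start[1], ranked$end[1], params)
  if (is.null(tb)) return(NULL)
  if (tb$identity < params@minIdentity || tb$coverage < params@minCoverage)
    return(NULL)
  mq <- mapqSE(b1, b2, tb$coverage)
  .alignmentRow(cand$name, cand$orient[[ranked$strand[1]]], tb,
                ranked$strand[1], mq, index, qual)
}

#' Align a single read (single-end)
#'
#' Full single-end pipeline: MEM seeding on both strands (with rescue),
#' mapping-region determination and merging, Smith-Waterman scoring of every
#' region, ranking, traceback of the best region, and acceptance filtering
#' (identity >= \code{minIdentity}, read coverage >= \code{minCoverage}).
#' The mapping quality uses the best and second-best region scores.
#'
#' @param read read sequence (character or \code{DNAString}).
#' @param index a [GenomeIndex-class].
#' @param params an [AlignerParams-class].
#' @param name read name for the SAM record.
#' @param qual optional base-quality string (carried through, never used in
#'   scoring).
#' @return A one-row data.frame in SAM column order (plus \code{score},
#'   \code{nm}, \code{identity}, \code{coverage} and concatenated coordinates
#'   \code{gpos}/\code{gend}); unaligned reads get FLAG 4.
#' @examples
#' idx <- buildGenomeIndex(c(chr = paste(rep("GATTACA", 30), collapse = "")))
#' alignReadSE(substr(as.character(referenceSequence(idx)[[1]]), 31, 80), idx)
#' @export
alignReadSE <- function(read, index, params = alignerParams(), name = "read",
                        qual = NULL) {
  cand <- .seCandidates(read, index, params, name)
  row <- .finishSE(cand, index, params, qual)
  if (is.null(row)) .unalignedRow(name, cand$read, qual) else row
}
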