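#' @import methods
NULL

#' Packed reference genome
#'
#' Concatenation of all reference records into a single 0-based coordinate
#' space, stored as integer base codes (A=0, C=1, G=2, T=3, N=4). Positions
#' that were N in the input are retained in the codes and act as a mask: no
#' exact-match seed and no aligned match may use them.
#'
#' @slot seqnames character, record identifiers in input order.
#' @slot seqlengths integer, per-record lengths in bases.
#' @slot offsets integer, 0-based start of each record in the concatenated
#'   text; \code{offsets[i] + seqlengths[i] == offsets[i+1]}.
#' @slot codes integer, the concatenated base codes.
#'
#' @seealso [packReference()], [buildGenomeIndex()]
#' @export
setClass("PackedReference",
  representation(seqnames = "character", seqlengths = "integer",
                 offsets = "integer", codes = "integer"))

setValidity("PackedReference", function(object) {
  msg <- character(0)
  k <- length(object@seqnames)
  if (k == 0L) msg <- c(msg, "at least one record is required")
  if (length(object@seqlengths) != k || length(object@offsets) != k)
    msg <- c(msg, "seqnames, seqlengths and offsets must have equal length")
  else {
    if (k > 1L && any(diff(object@offsets) <= 0L))
      msg <- c(msg, "offsets must be strictly increasing")
    if (!identical(object@offsets, c(0L, cumsum(object@seqlengths))[seq_len(k)]))
      msg <- c(msg, "offsets[i] + seqlengths[i] must equal offsets[i+1]")
    if (length(object@codes) != sum(object@seqlengths))
      msg <- c(msg, "codes length must equal the total reference length")
  }
  if (length(object@codes) && (min(object@codes) < 0L || max(object@codes) > 4L))
    msg <- c(msg, "codes must be in 0..4")
  if (length(msg)) msg else TRUE
})

#' FM-index over one direction of the packed text
#'
#' Burrows-Wheeler transform of text-plus-terminator (2-bit packed; the
#' terminator's slot is stored separately in \code{dollar} and skipped by all
#' occurrence counts), cumulative counts \code{C} over \{A,C,G,T\}, and
#' occurrence checkpoints sampled every \code{u} BWT positions. A query for
#' \code{Occ(a, i)} reads the nearest checkpoint and counts at most
#' \code{u - 1} packed symbols on the fly.
#'
#' @slot bwt raw, 2-bit packed BWT of length \code{textLength + 1}.
#' @slot dollar integer, BWT position of the terminator.
#' @slot C integer(4), number of text characters lexicographically smaller
#'   than each base (terminator excluded).
#' @slot counts integer(4), total occurrences of each base.
#' @slot occCheckpoints integer matrix, 4 x (textLength/u + 1).
#' @slot u integer, occurrence sampling factor.
#' @slot textLength integer, number of bases indexed (terminator excluded).
#' @export
setClass("FMIndex",
  representation(bwt = "raw", dollar = "integer", C = "integer",
                 counts = "integer", occCheckpoints = "matrix",
                 u = "integer", textLength = "integer"),
  prototype(bwt = raw(1), dollar = 0L, C = integer(4), counts = integer(4),
            occCheckpoints = matrix(0L, 4, 1), u = 1L, textLength = 0L))

setValidity("FMIndex", function(object) {
  msg <- character(0)
  if (object@u < 1L) msg <- c(msg, "u must be >= 1")
  if (is.unsorted(object@C)) msg <- c(msg, "C must be non-decreasing")
  if (sum(object@counts) != object@textLength)
    msg <- c(msg, "per-base counts must sum to the text length")
  if (length(msg)) msg else TRUE
})

#' Sampled (reduced) suffix array
#'
#' Text-position sampling: suffix-array entries whose text position is a
#' multiple of \code{v} (plus the terminator suffix) are retained, so locating
#' any occurrence needs at most \code{v} last-to-first (LF) steps; the walked
#' step count is added back to the retained position.
#'
#' @slot v integer, sampling factor.
#' @slot marks raw, bit vector over suffix-array indices flagging retained
#'   entries (padded to 64-bit blocks).
#' @slot rankBlocks integer, cumulative popcounts per 64-bit block of
#'   \code{marks}.
#' @slot values integer, retained text positions in suffix-array order.
#' @slot length integer, number of suffix-array entries (textLength + 1).
#' @export
setClass("SampledSA",
  representation(v = "integer", marks = "raw", rankBlocks = "integer",
                 values = "integer", length = "integer"),
  prototype(v = 1L, marks = raw(8), rankBlocks = 0L, values = integer(0),
            length = 1L))

setValidity("SampledSA", function(object) {
  msg <- character(0)
  if (object@v < 1L) msg <- c(msg, "v must be >= 1")
  if (length(object@values) &&
      (min(object@values) < 0L || max(object@values) > object@length - 1L))
    msg <- c(msg, "retained values must be valid text positions")
  if (length(msg)) msg else TRUE
})

#' Suffix-array interval
#'
#' Inclusive index range \code{[lo, hi]} into suffix-array order; its width
#' (\code{hi - lo + 1}, or 0 when \code{lo > hi}) equals the number of
#' occurrences of the searched substring.
#'
#' @slot lo,hi integer suffix-array indices; \code{lo > hi} encodes the empty
#'   interval.
#' @export
setClass("SAInterval", representation(lo = "integer", hi = "integer"))

#' Genome index: packed reference plus FM-indexes over both text directions
#'
#' The forward-text index answers backward search for oriented read
#' substrings; the reversed-text index makes left-to-right longest-exact-match
#' extension a backward search, so seed generation needs only unidirectional
#' substring search. Only the forward strand is indexed; reads are queried
#' as-is and as their reverse complement.
#'
#' @slot reference a [PackedReference-class].
#' @slot fwd,rev [FMIndex-class] over the forward and reversed text.
#' @slot fwdSSA,revSSA [SampledSA-class] companions.
#' @slot nCumsum numeric, cumulative count of N positions (length
#'   \code{totalLength + 1}) for O(1) mask-overlap checks.
#' @seealso [buildGenomeIndex()]
#' @export
setClass("GenomeIndex",
  representation(reference = "PackedReference",
                 fwd = "FMIndex", fwdSSA = "SampledSA",
                 rev = "FMIndex", revSSA = "SampledSA",
                 nCumsum = "numeric"))

#' Aligner parameters
#'
#' All tunables in one validated object. Defaults are the aligner's study
#' conditions: per-base error probability 2\%, missing probability 4\%, seed
#' size clamps 13/49, at most 1024 occurrences kept per MEM, occurrence
#' sampling u = 128, suffix-array sampling v = 8, scoring +1/-3 with gap
#' open 5 and gap extend 2, minimal region score 30, identity >= 90\% and
#' read coverage >= 80\% for a reported alignment, and insert-size deviation
#' multiplier k = 4 for paired-end mapping.
#'
#' @slot errProb numeric, per-base error probability p.
#' @slot missProb numeric, allowed probability m of underestimating errors.
#' @slot qLow,qHigh integer, clamps on the estimated minimal seed size.
#' @slot maxOcc integer, occurrences kept per MEM (h).
#' @slot u,v integer, index sampling factors.
#' @slot matchScore,mismatchPenalty,gapOpenPenalty,gapExtendPenalty integer,
#'   local-alignment scoring scheme (penalties are positive).
#' @slot minScore integer, minimal mapping-region score.
#' @slot minIdentity,minCoverage numeric, alignment acceptance filters.
#' @slot insertMean,insertSd numeric, paired-end insert-size model.
#' @slot insertK numeric, deviation multiplier; the maximal mapping distance
#'   is \code{insertMean + insertK * insertSd}.
#' @slot workers integer, worker count for batch alignment.
#' @seealso [alignerParams()]
#' @export
setClass("AlignerParams",
  representation(errProb = "numeric", missProb = "numeric",
                 qLow = "integer", qHigh = "integer", maxOcc = "integer",
                 u = "integer", v = "integer",
                 matchScore = "integer", mismatchPenalty = "integer",
                 gapOpenPenalty = "integer", gapExtendPenalty = "integer",
                 minScore = "integer", minIdentity = "numeric",
                 minCoverage = "numeric", insertMean = "numeric",
                 insertSd = "numeric", insertK = "numeric",
                 workers = "integer"))

setValidity("AlignerParams", function(object) {
  msg <- character(0)
  if (object@errProb <= 0 || object@errProb >= 1)
    msg <- c(msg, "errProb must be in (0, 1)")
  if (object@missProb <= 0 || object@missProb >= 1)
    msg <- c(msg, "missProb must be in (0, 1)")
  if (object@qLow < 1L || object@qLow > object@qHigh)
    msg <- c(msg, "need 1 <= qLow <= qHigh")
  if (object@maxOcc < 1L) msg <- c(msg, "maxOcc must be >= 1")
  if (object@u < 1L || object@v < 1L) msg <- c(msg, "u and v must be >= 1")
  if (object@matchScore < 1L) msg <- c(msg, "matchScore must be positive")
  if (object@mismatchPenalty <= object@matchScore ||
      object@gapOpenPenalty <= object@matchScore ||
      object@gapExtendPenalty <= object@matchScore)
    msg <- c(msg, paste("each penalty must exceed the match score (required",
                        "for the 2|S| alignment-length bound)"))
  if (object@minScore < 1L) msg <- c(msg, "minScore must be positive")
  if (object@minIdentity < 0 || object@minIdentity > 1 ||
      object@minCoverage < 0 || object@minCoverage > 1)
    msg <- c(msg, "minIdentity and minCoverage must be in [0, 1]")
  if (object@insertSd < 0) msg <- c(msg, "insertSd must be >= 0")
  if (object@insertK < 0) msg <- c(msg, "insertK must be >= 0")
  if (object@workers < 1L) msg <- c(msg, "workers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn AlignerParams-class constructor; any slot can be overridden by
#'   name, everything else keeps its default.
#' @param ... named overrides of the slots documented above (integers may be
#'   given as plain numerics).
#' @return An \code{AlignerParams} object.
#' @examples
#' p <- alignerParams(minScore = 25, insertMean = 500, insertSd = 50)
#' @export
alignerParams <- function(...) {
  defaults <- list(errProb = 0.02, missProb = 0.04, qLow = 13L, qHigh = 49L,
                   maxOcc = 1024L, u = 128L, v = 8L,
                   matchScore = 1L, mismatchPenalty = 3L,
                   gapOpenPenalty = 5L, gapExtendPenalty = 2L,
                   minScore = 30L, minIdentity = 0.90, minCoverage = 0.80,
                   insertMean = 1000, insertSd = 50, insertK = 4,
                   workers = 1L)
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  ints <- c("qLow", "qHigh", "maxOcc", "u", "v", "matchScore",
            "mismatchPenalty", "gapOpenPenalty", "gapExtendPenalty",
            "minScore", "workers")
  defaults[ints] <- lapply(defaults[ints], function(x) as.integer(round(x)))
  do.call(new, c(list("AlignerParams"), defaults))
}
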