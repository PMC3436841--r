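# Index construction and substring search: pack the reference, build the
# suffix array and BWT, derive the sampled FM-index and sampled suffix array,
# and answer backward-search / locate queries.

.asSeqStrings <- function(x) {
  if (is(x, "DNAStringSet")) {
    stats::setNames(as.character(x), names(x))
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    names(s) <- sub("\\s.*$", "", names(s))
    stats::setNames(as.character(s), names(s))
  } else if (is.character(x)) {
    x
  } else stop("expected a DNAStringSet, a character vector or a FASTA path")
}

#' Pack reference records into one coordinate space
#'
#' Concatenates all records (order preserved) into a single 0-based text over
#' \{A,C,G,T\} with N positions flagged; the alphabet is validated and the
#' offending record and offset are reported for any other character.
#'
#' @param x a named character vector of sequences, a
#'   \code{Biostrings::DNAStringSet}, or the path to a (multi-record,
#'   line-wrapped, case-insensitive) FASTA file.
#' @return A [PackedReference-class].
#' @examples
#' ref <- packReference(c(chr1 = "ACGT", chr2 = "GGGG"))
#' refOffsets(ref)
#' @export
packReference <- function(x) {
  seqs <- .asSeqStrings(x)
  if (length(seqs) == 0L) stop("no reference records")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(nchar(seqs) == 0L)) stop("empty reference record: ",
                                   names(seqs)[which(nchar(seqs) == 0L)[1]])
  codes <- lapply(seqs, cpp_encode)
  for (i in seq_along(codes)) {
    bad <- which(codes[[i]] < 0L)
    if (length(bad))
      stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                   substr(seqs[i], bad[1], bad[1]), names(seqs)[i], bad[1] - 1L))
  }
  lens <- vapply(codes, length, integer(1))
  new("PackedReference",
      seqnames = names(seqs),
      seqlengths = unname(lens),
      offsets = c(0L, cumsum(unname(lens)))[seq_along(lens)],
      codes = unlist(codes, use.names = FALSE))
}

.textCodes <- function(text) {
  if (is(text, "PackedReference")) return(text@codes)
  if (is(text, "DNAString") || is(text, "DNAStringSet"))
    text <- as.character(text)[1]
  if (!is.character(text) || length(text) != 1L || nchar(text) == 0L)
    stop("text must be a single non-empty base string")
  codes <- cpp_encode(text)
  if (any(codes < 0L)) stop("text contains a character outside {A,C,G,T,N}")
  codes
}

#' Build the suffix array of a text
#'
#' Positions of all suffixes of \code{text} plus an appended terminator
#' (lexicographically smallest), in increasing lexicographic order. N bases
#' sort as the placeholder A, matching index construction; matches touching N
#' are invalidated downstream by the N-mask.
#'
#' @param text a base string, \code{DNAString} or [PackedReference-class].
#' @return Integer vector of length \code{nchar(text) + 1}, 0-based positions.
#' @examples
#' buildSuffixArray("GATTACA")  # 7 6 4 1 5 0 3 2
#' @export
buildSuffixArray <- function(text) {
  codes <- .textCodes(text)
  cpp_suffix_array(pmin(codes, 3L))
}

#' Burrows-Wheeler transform from a suffix array
#'
#' Last column of the sorted cyclic-rotation matrix of \code{text} plus the
#' terminator, i.e. the character preceding each suffix (the terminator where
#' the suffix starts at 0).
#'
#' @inheritParams buildSuffixArray
#' @param sa the suffix array of \code{text} as from [buildSuffixArray()].
#' @return A single string over \{A,C,G,T,$\}.
#' @examples
#' bwtFromSuffixArray("GATTACA", buildSuffixArray("GATTACA"))  # "ACTGA$TA"
#' @export
bwtFromSuffixArray <- function(text, sa) {
  codes <- .textCodes(text)
  n <- length(codes)
  if (length(sa) != n + 1L || !setequal(sa, 0:n))
    stop("sa is not a valid suffix array of text")
  prev <- (sa + n) %% (n + 1L)
  chars <- strsplit(paste0(cpp_decode(codes), "$"), "")[[1]]
  paste(chars[prev + 1L], collapse = "")
}

.fmFromPacked <- function(bwtPacked, dollar, n, u) {
  ckpt <- cpp_fm_checkpoints(bwtPacked, dollar, n + 1L, u)
  counts <- ckpt$counts
  fm <- new("FMIndex")
  fm@bwt <- bwtPacked
  fm@dollar <- as.integer(dollar)
  fm@C <- c(0L, cumsum(counts)[1:3])  # new() cannot take C=: partial-matches Class
  fm@counts <- counts
  fm@occCheckpoints <- ckpt$checkpoints
  fm@u <- as.integer(u)
  fm@textLength <- as.integer(n)
  validObject(fm)
  fm
}

#' Build an FM-index from a BWT string
#'
#' @param bwt the BWT including its terminator \code{$}, as returned by
#'   [bwtFromSuffixArray()].
#' @param u occurrence sampling factor: checkpoints of \code{Occ} are stored
#'   every \code{u} positions, so a query counts at most \code{u - 1} symbols
#'   on the fly (default 128).
#' @return An [FMIndex-class].
#' @export
buildFMIndex <- function(bwt, u = 128L) {
  u <- as.integer(u)
  if (is.na(u) || u < 1L) stop("u must be >= 1")
  chars <- strsplit(bwt, "")[[1]]
  dollar <- which(chars == "$")
  if (length(dollar) != 1L) stop("bwt must contain exactly one '$'")
  codes <- cpp_encode(paste(chars, collapse = ""))
  codes[dollar] <- 0L
  if (any(codes < 0L | codes > 3L)) stop("bwt contains characters outside {A,C,G,T,$}")
  .fmFromPacked(cpp_pack_codes(codes), dollar - 1L, length(chars) - 1L, u)
}

#' Build a sampled suffix array
#'
#' Retains the entries whose text position is a multiple of \code{v} (plus the
#' terminator suffix), so that [locateOccurrences()] resolves any entry with at
#' most \code{v} LF steps.
#'
#' @param sa a suffix array from [buildSuffixArray()].
#' @param v sampling factor (default 8).
#' @return A [SampledSA-class].
#' @export
buildSampledSA <- function(sa, v = 8L) {
  v <- as.integer(v)
  if (is.na(v) || v < 1L) stop("v must be >= 1")
  s <- cpp_ssa_build(as.integer(sa), v)
  new("SampledSA", v = v, marks = s$marks, rankBlocks = s$rankBlocks,
      values = s$values, length = length(sa))
}

#' Build the full genome index
#'
#' Packs the reference and builds FM-indexes plus sampled suffix arrays over
#' both the forward and the reversed concatenated text. The reversed-text
#' index turns left-to-right exact-match extension of a read into a backward
#' search, so MEM seeding needs only unidirectional substring search.
#'
#' @param x reference input accepted by [packReference()], or an existing
#'   [PackedReference-class].
#' @param u,v sampling factors for the occurrence checkpoints and the sampled
#'   suffix array (defaults 128 and 8).
#' @return A [GenomeIndex-class].
#' @examples
#' idx <- buildGenomeIndex(c(chr1 = "GATTACAGATTACA"))
#' @export
buildGenomeIndex <- function(x, u = 128L, v = 8L) {
  ref <- if (is(x, "PackedReference")) x else packReference(x)
  placeholder <- pmin(ref@codes, 3L)
  buildOne <- function(codes) {
    sa <- cpp_suffix_array(codes)
    b <- cpp_bwt_build(codes, sa)
    list(fm = .fmFromPacked(b$bwt, b$dollar, length(codes), as.integer(u)),
         ssa = buildSampledSA(sa, v))
  }
  fwd <- buildOne(placeholder)
  rev <- buildOne(rev(placeholder))
  nCum <- c(0, cumsum(ref@codes == 4L))
  new("GenomeIndex", reference = ref,
      fwd = fwd$fm, fwdSSA = fwd$ssa, rev = rev$fm, revSSA = rev$ssa,
      nCumsum = nCum)
}

#' Backward search for a pattern
#'
#' Computes the suffix-array interval of all occurrences of \code{pattern},
#' prepending one character at a time from the rightmost suffix (interval
#' initialized to \code{[0, |T|]}); the recursion stops as soon as the
#' interval empties. A pattern containing N matches nothing.
#'
#' @param fm an [FMIndex-class] (or a [GenomeIndex-class], whose forward index
#'   is used).
#' @param pattern a non-empty base string.
#' @return A [SAInterval-class]; its \code{width()} is the occurrence count.
#' @examples
#' idx <- buildGenomeIndex(c(chr = "GATTACA"))
#' width(backwardSearch(idx, "A"))   # 3
#' @export
backwardSearch <- function(fm, pattern) {
  if (is(fm, "GenomeIndex")) fm <- fm@fwd
  pat <- cpp_encode(pattern)
  if (length(pat) == 0L) stop("pattern must be non-empty")
  if (any(pat < 0L)) stop("pattern contains a character outside {A,C,G,T,N}")
  if (any(pat > 3L)) return(new("SAInterval", lo = 1L, hi = 0L))
  r <- cpp_backward_search(fm@bwt, fm@dollar, fm@occCheckpoints, fm@u, fm@C,
                           fm@textLength, pat)
  new("SAInterval", lo = r[1], hi = r[2])
}

#' Count occurrences of a base in a BWT prefix
#'
#' \code{Occ(a, i)}: occurrences of base \code{a} in \code{B_T[0, i]} (the
#' terminator is never counted), answered from the nearest checkpoint.
#'
#' @inheritParams backwardSearch
#' @param base one of "A", "C", "G", "T".
#' @param i 0-based inclusive BWT position; \code{i < 0} gives 0.
#' @return Integer count.
#' @export
occCount <- function(fm, base, i) {
  if (is(fm, "GenomeIndex")) fm <- fm@fwd
  a <- match(toupper(base), c("A", "C", "G", "T")) - 1L
  if (is.na(a)) stop("base must be one of A, C, G, T")
  cpp_occ(fm@bwt, fm@dollar, fm@occCheckpoints, fm@u, fm@C, fm@textLength,
          a, as.integer(i))
}

#' Locate occurrences from a suffix-array interval
#'
#' Resolves up to \code{limit} entries of the interval (smallest suffix-array
#' indices first) to text positions, each by walking at most \code{v} LF steps
#' to a retained suffix-array sample.
#'
#' @param fm an [FMIndex-class] or [GenomeIndex-class].
#' @param ssa the matching [SampledSA-class]; taken from the index when
#'   \code{fm} is a [GenomeIndex-class] and \code{ssa} is missing.
#' @param interval a [SAInterval-class] from [backwardSearch()].
#' @param limit maximum number of occurrences to resolve (>= 1).
#' @return Integer vector of 0-based text positions (in suffix-array order;
#'   sort for positional order).
#' @examples
#' idx <- buildGenomeIndex(c(chr = "GATTACA"))
#' sort(locateOccurrences(idx, interval = backwardSearch(idx, "A")))  # 1 4 6
#' @export
locateOccurrences <- function(fm, ssa, interval, limit = 1024L) {
  if (is(fm, "GenomeIndex")) {
    if (missing(ssa)) ssa <- fm@fwdSSA
    fm <- fm@fwd
  }
  if (limit < 1L) stop("limit must be >= 1")
  if (interval@lo > interval@hi) return(integer(0))
  cpp_locate(fm@bwt, fm@dollar, fm@occCheckpoints, fm@u, fm@C, fm@textLength,
             ssa@marks, ssa@rankBlocks, ssa@values,
             interval@lo, interval@hi, as.integer(limit))
}

#' Predict index memory footprints
#'
#' Closed-form memory cost, in bits, of the index variants for a text of
#' \code{totalLength} bases over a 4-letter alphabet: the full suffix array
#' (\code{|T| ceil(log2 |T|)}), the full FM-index plus suffix array, the
#' reduced FM-index with occurrence sampling \code{u}, the reduced suffix
#' array with sampling \code{v}, and their total
#' \code{(|S|+|T|) ceil(log2 |S|) + |T| (|S|/u + 1/v) ceil(log2 |T|)} with
#' \code{|S| = 4}.
#'
#' @param totalLength text length in bases (>= 2).
#' @param u,v sampling factors (defaults 128 and 8).
#' @param variant which footprint to evaluate.
#' @return Memory in bits (numeric).
#' @examples
#' predictIndexMemory(3e9, variant = "full_sa") / 8 / 1e9   # ~12 GB
#' predictIndexMemory(3e9, 128, 8, "reduced_total") / 8 / 1e9  # ~2.6 GB
#' @export
predictIndexMemory <- function(totalLength, u = 128, v = 8,
                               variant = c("reduced_total", "full_sa",
                                           "full_index", "reduced_fm",
                                           "reduced_sa")) {
  variant <- match.arg(variant)
  n <- as.numeric(totalLength)
  if (n < 2) stop("totalLength must be >= 2")
  logT <- ceiling(log2(n))
  logS <- 2  # ceil(log2 4)
  sigma <- 4
  switch(variant,
    full_sa = n * logT,
    full_index = sigma * n * logT + n * logT,
    reduced_fm = sigma * logS + n * (sigma * logT / u + logS),
    reduced_sa = n * logT / v,
    reduced_total = (sigma + n) * logS + n * (sigma / u + 1 / v) * logT)
}

# reconstruct the text from an FM-index by repeated LF mapping (used by the
# conservation tests; O(n * u), fine at test scale)
.reconstructText <- function(fm) {
  n <- fm@textLength
  out <- integer(n)
  i <- 0L
  for (k in seq(n, 1L)) {
    out[k] <- .bwtCode(fm, i)
    i <- cpp_lf(fm@bwt, fm@dollar, fm@occCheckpoints, fm@u, fm@C, n, i)
  }
  cpp_decode(out)
}

.bwtCode <- function(fm, i) {
  byte <- as.integer(fm@bwt[i %/% 4L + 1L])
  bitwAnd(bitwShiftR(byte, 2L * (i %% 4L)), 3L)
}
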