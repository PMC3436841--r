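#' @rdname PackedReference-class
#' @param x,object a \code{PackedReference} (or, for \code{totalLength},
#'   anything carrying a reference).
#' @export
setGeneric("refNames", function(x) standardGeneric("refNames"))

#' @rdname PackedReference-class
#' @export
setGeneric("refLengths", function(x) standardGeneric("refLengths"))

#' @rdname PackedReference-class
#' @export
setGeneric("refOffsets", function(x) standardGeneric("refOffsets"))

#' @rdname PackedReference-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname PackedReference-class
#' @export
setGeneric("referenceSequence", function(x) standardGeneric("referenceSequence"))

setMethod("refNames", "PackedReference", function(x) x@seqnames)
setMethod("refLengths", "PackedReference", function(x) {
  stats::setNames(x@seqlengths, x@seqnames)
})
setMethod("refOffsets", "PackedReference", function(x) {
  stats::setNames(x@offsets, x@seqnames)
})
setMethod("totalLength", "PackedReference", function(x) length(x@codes))

setMethod("referenceSequence", "PackedReference", function(x) {
  seqs <- vapply(seq_along(x@seqnames), function(i) {
    from <- x@offsets[i] + 1L
    cpp_decode(x@codes[from:(from + x@seqlengths[i] - 1L)])
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- x@seqnames
  out
})

setMethod("refNames", "GenomeIndex", function(x) refNames(x@reference))
setMethod("refLengths", "GenomeIndex", function(x) refLengths(x@reference))
setMethod("refOffsets", "GenomeIndex", function(x) refOffsets(x@reference))
setMethod("totalLength", "GenomeIndex", function(x) totalLength(x@reference))
setMethod("totalLength", "FMIndex", function(x) x@textLength)

#' @rdname SAInterval-class
#' @param x a \code{SAInterval}.
#' @importFrom BiocGenerics width
#' @export
setMethod("width", "SAInterval", function(x) {
  if (x@lo > x@hi) 0L else x@hi - x@lo + 1L
})

setMethod("show", "PackedReference", function(object) {
  cat(sprintf("PackedReference: %d record(s), %s bases (%s N)\n",
              length(object@seqnames),
              format(totalLength(object), big.mark = ","),
              format(sum(object@codes == 4L), big.mark = ",")))
  k <- min(5L, length(object@seqnames))
  for (i in seq_len(k))
    cat(sprintf("  %s: %d bp at offset %d\n", object@seqnames[i],
                object@seqlengths[i], object@offsets[i]))
  if (length(object@seqnames) > k) cat("  ...\n")
})

setMethod("show", "FMIndex", function(object) {
  cat(sprintf("FMIndex: %s bases, occurrence checkpoints every u = %d\n",
              format(object@textLength, big.mark = ","), object@u))
})

setMethod("show", "SampledSA", function(object) {
  cat(sprintf("SampledSA: %s entries, sampling factor v = %d (%s retained)\n",
              format(object@length, big.mark = ","), object@v,
              format(length(object@values), big.mark = ",")))
})

setMethod("show", "SAInterval", function(object) {
  cat(sprintf("SAInterval [%d, %d], width %d\n", object@lo, object@hi,
              width(object)))
})

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex (forward + reversed text)\n")
  show(object@reference)
  cat(sprintf("  u = %d, v = %d\n", object@fwd@u, object@fwdSSA@v))
})

setMethod("show", "AlignerParams", function(object) {
  cat("AlignerParams:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-16s %s\n", s, format(slot(object, s))))
})
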