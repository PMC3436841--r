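# Heuristic mapping-quality approximation from the ranked region scores.

#' Single-end mapping quality
#'
#' Approximated as \code{250 * (b1 - b2) / b1 * r}, floored and clamped to
#' \code{[0, 250]}, where \code{b1} and \code{b2} are the best and second-best
#' local alignment scores of the read's mapping regions and \code{r} is the
#' fraction of read bases in the final alignment. \code{b2 = 0} when a single
#' region exists (no competitor means maximal confidence).
#'
#' @param b1 best local alignment score (> 0).
#' @param b2 second best local alignment score (0 if none); \code{b1 >= b2}.
#' @param r aligned read bases divided by read length, in \code{[0, 1]}.
#' @return Integer mapping quality in \code{[0, 250]}.
#' @examples
#' mapqSE(100, 50, 0.8)  # 100
#' mapqSE(100, 100, 1)   # 0
#' @export
mapqSE <- function(b1, b2, r) {
  if (b1 <= 0) stop("b1 must be positive (unaligned reads have no mapq)")
  if (b2 < 0 || b2 > b1) stop("need 0 <= b2 <= b1")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  mq <- floor(250 * (b1 - b2) / b1 * r)
  as.integer(max(0, min(250, mq)))
}

#' Paired-end mapping quality
#'
#' A read paired through seed pairing (or whose independently best alignments
#' already satisfied the insert-size constraint) keeps its single-end mapping
#' quality. A read rescued by its mate gets \code{floor(r * mateMapq)}, where
#' \code{r} is its own aligned-base fraction and \code{mateMapq} the mate's
#' single-end mapping quality.
#'
#' @param pairing one of \code{"seed_paired"}, \code{"distance_ok"},
#'   \code{"rescued"}.
#' @param selfSeMapq the read's own single-end mapping quality.
#' @param mateSeMapq the mate's single-end mapping quality (rescue case).
#' @param r the read's aligned-base fraction.
#' @return Integer mapping quality in \code{[0, 250]}.
#' @examples
#' mapqPE("seed_paired", selfSeMapq = 37)             # 37
#' mapqPE("rescued", mateSeMapq = 200, r = 0.9)       # 180
#' @export
mapqPE <- function(pairing = c("seed_paired", "distance_ok", "rescued"),
                   selfSeMapq = NA_integer_, mateSeMapq = NA_integer_, r = 1) {
  pairing <- match.arg(pairing)
  if (pairing %in% c("seed_paired", "distance_ok")) {
    if (is.na(selfSeMapq)) stop("selfSeMapq required for paired reads")
    return(as.integer(max(0, min(250, selfSeMapq))))
  }
  if (is.na(mateSeMapq)) stop("mateSeMapq required for rescued reads")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  as.integer(max(0, min(250, floor(r * mateSeMapq))))
}
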