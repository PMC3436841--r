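# Standard-format input, SAM output, and batch alignment with a dynamic
# parallel-execution contract.

#' Read sequencing reads from FASTA or FASTQ
#'
#' Multi-record, line-wrapped, case-insensitive input; format is taken from
#' the file content (leading \code{@} means FASTQ) unless given. In paired
#' mode the two files must hold the same number of records, yielded together.
#'
#' @param path path to the reads (mate 1 in paired mode).
#' @param path2 optional path to the mate-2 reads.
#' @param format "auto" (default), "fasta" or "fastq".
#' @return A list with character vectors \code{names}, \code{seqs},
#'   \code{quals} (NULL for FASTA) and, in paired mode, \code{names2},
#'   \code{seqs2}, \code{quals2}.
#' @export
readReads <- function(path, path2 = NULL, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  readOne <- function(p) {
    if (!file.exists(p)) stop("no such file: ", p)
    fmt <- format
    if (fmt == "auto") {
      first <- readLines(p, n = 1L)
      fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    }
    if (fmt == "fastq") {
      s <- Biostrings::readDNAStringSet(p, format = "fastq",
                                        with.qualities = TRUE)
      quals <- as.character(S4Vectors::mcols(s)$qualities)
    } else {
      s <- Biostrings::readDNAStringSet(p, format = "fasta")
      quals <- NULL
    }
    list(names = unname(sub("\\s.*$", "", names(s))),
         seqs = unname(as.character(s)),
         quals = if (is.null(quals)) NULL else unname(quals))
  }
  r1 <- readOne(path)
  if (is.null(path2)) return(r1)
  r2 <- readOne(path2)
  if (length(r1$seqs) != length(r2$seqs))
    stop(sprintf("mate files differ in record count (%d vs %d)",
                 length(r1$seqs), length(r2$seqs)))
  c(r1, stats::setNames(r2, c("names2", "seqs2", "quals2")))
}

#' Write alignment results as SAM
#'
#' Emits a valid header (\code{@HD}, one \code{@SQ} per reference record,
#' \code{@PG} with the command line) followed by the records; aligned rows
#' carry \code{AS:i} (alignment score) and \code{NM:i} (edit distance over the
#' aligned columns) tags. Positions are 1-based; unaligned reads keep FLAG
#' 0x4, RNAME \code{*} and POS 0.
#'
#' @param results data.frame of alignment rows as produced by
#'   [alignReads()], [alignReadSE()] or [alignPair()].
#' @param reference the [PackedReference-class] or [GenomeIndex-class] the
#'   reads were aligned to.
#' @param path output file path ("" writes to stdout).
#' @param commandLine string recorded in the \code{@PG} CL field.
#' @return Invisibly, the number of records written.
#' @export
writeSAM <- function(results, reference, path = "",
                     commandLine = "memalign align") {
  ref <- if (is(reference, "GenomeIndex")) reference@reference else reference
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref@seqnames, ref@seqlengths),
              sprintf("@PG\tID:memalign\tPN:memalign\tVN:%s\tCL:%s",
                      as.character(utils::packageVersion("memalign")),
                      commandLine))
  body <- character(0)
  if (nrow(results) > 0L) {
    tags <- ifelse(is.na(results$score), "",
                   sprintf("\tAS:i:%d\tNM:i:%d", results$score, results$nm))
    body <- paste0(results$qname, "\t", results$flag, "\t", results$rname,
                   "\t", results$pos, "\t", results$mapq, "\t", results$cigar,
                   "\t", results$rnext, "\t", results$pnext, "\t",
                   results$tlen, "\t", results$seq, "\t", results$qual, tags)
  }
  writeLines(c(header, body), path)
  invisible(length(body))
}

#' Run an alignment function over a read stream
#'
#' Work units (single reads or single pairs) are dynamically assigned to
#' workers; results are reassembled in input order, so the output is
#' independent of the worker count (and byte-identical for one worker).
#'
#' @param items list of work units.
#' @param alignFn function of one work unit.
#' @param workers worker count (>= 1; forked processes when > 1).
#' @return List of results in input order.
#' @export
runParallel <- function(items, alignFn, workers = 1L) {
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("workers must be >= 1")
  res <- if (workers == 1L) lapply(items, alignFn)
         else parallel::mclapply(items, alignFn, mc.cores = workers,
                                 mc.preschedule = FALSE)
  bad <- vapply(res, inherits, logical(1), what = "try-error")
  if (any(bad)) stop("worker failure: ", attr(res[[which(bad)[1]]], "condition")$message)
  res
}

#' Align a batch of reads (single- or paired-end)
#'
#' Applies [alignReadSE()] per read, or [alignPair()] per pair when
#' \code{reads2} is given, over \code{params@workers} workers, and binds the
#' SAM-ready rows in input order.
#'
#' @param index a [GenomeIndex-class].
#' @param reads character vector of read sequences (or the list returned by
#'   [readReads()], in which case names, mates and qualities are taken from
#'   it).
#' @param reads2 optional character vector of mate-2 sequences.
#' @param params an [AlignerParams-class].
#' @param names optional read names (defaults to \code{read1}, \code{read2},
#'   ...).
#' @param quals,quals2 optional quality strings.
#' @return A data.frame of alignment rows (two per pair in paired mode, mate 1
#'   first), plus a \code{pairing} column in paired mode.
#' @export
alignReads <- function(index, reads, reads2 = NULL, params = alignerParams(),
                       names = NULL, quals = NULL, quals2 = NULL) {
  if (is.list(reads) && !is.null(reads$seqs)) {
    rr <- reads
    reads <- rr$seqs; names <- rr$names; quals <- rr$quals
    if (!is.null(rr$seqs2)) { reads2 <- rr$seqs2; quals2 <- rr$quals2 }
  }
  n <- length(reads)
  if (is.null(names)) names <- paste0("read", seq_len(n))
  paired <- !is.null(reads2)
  if (paired) names <- sub("/[12]$", "", names)  # mate suffixes live in FLAG
  if (paired && length(reads2) != n)
    stop("reads and reads2 must have equal length")
  items <- seq_len(n)
  fn <- if (paired) {
    function(i) {
      pr <- alignPair(reads[i], reads2[i], index, params, names[i],
                      if (is.null(quals)) NULL else quals[i],
                      if (is.null(quals2)) NULL else quals2[i])
      out <- rbind(pr$aln1, pr$aln2)
      out$pairing <- pr$pairing
      out
    }
  } else {
    function(i) alignReadSE(reads[i], index, params, names[i],
                            if (is.null(quals)) NULL else quals[i])
  }
  res <- runParallel(items, fn, params@workers)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
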