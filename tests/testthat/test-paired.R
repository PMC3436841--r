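# Paired-end pipeline: seed pairing, concordance, rescue, flags.

test_that("ungapped mapping position estimate", {
  expect_equal(estimateMappingPosition(
    data.frame(readOffset = 20L, genomePos = 1000L)), 980L)
  expect_equal(estimateMappingPosition(
    data.frame(readOffset = 0L, genomePos = 1234L)), 1234L)
})

test_that("seed pairing enforces strand, record and distance constraints", {
  gi <- smallIndex()
  params <- alignerParams(insertMean = 1000, insertSd = 50, insertK = 4)
  maxDist <- 1000 + 4 * 50
  slack <- indelSlack(200L, params) * 2L
  mk <- function(pos, strand) data.frame(readOffset = 0L, genomePos = pos,
                                         length = 30L, strand = strand,
                                         stringsAsFactors = FALSE)
  # concordant FR pair at the mean insert
  ok <- pairSeeds(mk(5000L, "forward"), mk(5800L, "reverse"),
                  200L, 200L, params, gi)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$dist, 1000L)
  # same strand: discarded
  ss <- pairSeeds(mk(5000L, "forward"), mk(5800L, "forward"),
                  200L, 200L, params, gi)
  expect_equal(nrow(ss), 0L)
  # beyond threshold + slack: discarded; at the boundary: kept
  far <- pairSeeds(mk(5000L, "forward"),
                   mk(5000L + maxDist + slack - 200L + 1L, "reverse"),
                   200L, 200L, params, gi)
  expect_equal(nrow(far), 0L)
  edge <- pairSeeds(mk(5000L, "forward"),
                    mk(5000L + maxDist + slack - 200L, "reverse"),
                    200L, 200L, params, gi)
  expect_equal(nrow(edge), 1L)
  # RF orientation (reverse leftmost): discarded
  rf <- pairSeeds(mk(5800L, "forward"), mk(5000L, "reverse"),
                  200L, 200L, params, gi)
  expect_equal(nrow(rf), 0L)
})

test_that("simulated concordant pairs come out properly paired", {
  g <- smallGenome(); gi <- smallIndex()
  sim <- simulatePairs(g, 60, readLength = 150, errorRate = 0,
                       insertMean = 600, insertSd = 40, seed = 21)
  params <- alignerParams(insertMean = 600, insertSd = 40)
  res <- alignReads(gi, sim$reads1, sim$reads2, params = params,
                    names = sim$names)
  expect_true(all(res$pairing %in%
                    c("distance_ok", "seed_paired", "rescued")))
  proper <- bitwAnd(res$flag, 2L) != 0L
  expect_gte(mean(proper), 0.999)
  # proper-pair invariants: opposite strands, same record, bounded TLEN
  maxDist <- 600 + 4 * 40
  for (nm in unique(res$qname[proper])) {
    pr <- res[res$qname == nm, ]
    expect_equal(nrow(pr), 2L)
    expect_true(xor(bitwAnd(pr$flag[1], 16L) != 0, bitwAnd(pr$flag[2], 16L) != 0))
    expect_equal(pr$rname[1], pr$rname[2])
    expect_lte(abs(pr$tlen[1]), maxDist)
    expect_equal(pr$tlen[1], -pr$tlen[2])
  }
  ev <- evaluateAlignments(res, sim$truth)
  expect_gte(ev$recall, 0.99)
})

test_that("a seed-free but alignable mate is rescued at the true position", {
  g <- smallGenome(); gi <- smallIndex()
  txt <- as.character(referenceSequence(g)[[1]])
  params <- alignerParams(insertMean = 600, insertSd = 40)
  start <- 40001L
  read1 <- substr(txt, start, start + 199L)
  mateStart <- start + 600L - 200L
  mateFwd <- strsplit(substr(txt, mateStart, mateStart + 199L), "")[[1]]
  # substitutions every 12 bases destroy every seed (max run 11 < Q_N = 17)
  # but leave ~92% identity, above the 90% acceptance filter
  for (k in seq(6, 200, by = 12))
    mateFwd[k] <- setdiff(c("A", "C", "G", "T"), mateFwd[k])[1]
  read2 <- revCompChar(paste(mateFwd, collapse = ""))
  expect_equal(nrow(seedsForRead(read2, gi, params)$seeds), 0L)
  pr <- alignPair(read1, read2, gi, params, name = "rescueme")
  expect_equal(pr$pairing, "rescued")
  expect_equal(pr$aln2$pos, mateStart)
  expect_equal(bitwAnd(pr$aln2$flag, 16L), 16L)
  expect_equal(pr$aln2$mapq,
               as.integer(floor(pr$aln2$coverage * pr$aln1$mapq)))

  # a mate of random sequence is not rescued
  pr2 <- alignPair(read1, randSeq(200), gi, params, name = "norescue")
  expect_equal(pr2$pairing, "unpaired")
  expect_equal(bitwAnd(pr2$aln2$flag, 4L), 4L)
  expect_equal(bitwAnd(pr2$aln1$flag, 8L), 8L)  # mate-unmapped on the anchor
})

test_that("paired flags and TLEN follow SAM semantics", {
  g <- smallGenome(); gi <- smallIndex()
  txt <- as.character(referenceSequence(g)[[1]])
  read1 <- substr(txt, 10001, 10150)
  read2 <- revCompChar(substr(txt, 10501, 10650))
  pr <- alignPair(read1, read2, gi, alignerParams(insertMean = 650,
                                                  insertSd = 30))
  expect_equal(sort(c(pr$aln1$flag, pr$aln2$flag)), c(99L, 147L))
  expect_equal(pr$aln1$tlen, 650L)
  expect_equal(pr$aln2$tlen, -650L)
  expect_equal(pr$aln1$rnext, "=")
  expect_equal(pr$aln1$pnext, pr$aln2$pos)
})

test_that("single-end mode is unchanged by the paired machinery", {
  g <- smallGenome(); gi <- smallIndex()
  sim <- simulatePairs(g, 10, readLength = 150, errorRate = 0.02,
                       insertMean = 600, insertSd = 40, seed = 22)
  se <- alignReads(gi, sim$reads1, names = paste0(sim$names, "/1"))
  for (i in seq_along(sim$reads1)) {
    one <- alignReadSE(sim$reads1[i], gi, name = paste0(sim$names[i], "/1"))
    expect_equal(se[i, ], one, ignore_attr = TRUE)
  }
})
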