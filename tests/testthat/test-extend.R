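# Mapping regions, affine-gap local alignment and the single-end pipeline.

test_that("indel slack follows the score budget with the 2|S| cap", {
  expect_equal(indelSlack(100), 32L)
  expect_equal(indelSlack(200), 82L)
  expect_equal(indelSlack(30), 0L)
  expect_equal(indelSlack(20), 0L)
  big <- alignerParams(minScore = 1, gapOpenPenalty = 2, gapExtendPenalty = 2,
                       mismatchPenalty = 2)
  expect_equal(indelSlack(10, big), 3L)  # floor((10-1-2)/2), under the cap
})

test_that("mapping regions contain the seed and clamp to record bounds", {
  set.seed(300)
  gi <- buildGenomeIndex(c(chr = randSeq(2000)))
  params <- alignerParams()
  seed <- data.frame(readOffset = 10L, genomePos = 1000L, length = 20L,
                     strand = "forward")
  r <- determineRegion(seed, 100L, params, gi)
  expect_equal(c(r$start, r$end), c(958L, 1122L))

  full <- data.frame(readOffset = 0L, genomePos = 500L, length = 100L,
                     strand = "forward")
  rf <- determineRegion(full, 100L, params, gi)
  expect_equal(c(rf$start, rf$end), c(500L - 32L, 600L + 32L))

  atStart <- data.frame(readOffset = 50L, genomePos = 3L, length = 30L,
                        strand = "forward")
  rs <- determineRegion(atStart, 100L, params, gi)
  expect_equal(rs$start, 0L)
  expect_true(rs$start <= atStart$genomePos &&
                rs$end >= atStart$genomePos + atStart$length)
})

test_that("overlapping same-strand regions merge; strands stay apart", {
  d <- data.frame(start = c(100L, 250L), end = c(300L, 500L),
                  strand = "forward")
  m <- mergeRegions(d)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 500L))

  disjoint <- data.frame(start = c(100L, 400L), end = c(200L, 500L),
                         strand = "forward")
  expect_equal(nrow(mergeRegions(disjoint)), 2L)

  strands <- data.frame(start = c(100L, 100L), end = c(300L, 300L),
                        strand = c("forward", "reverse"))
  expect_equal(nrow(mergeRegions(strands)), 2L)
})

test_that("local alignment scores match the worked examples", {
  expect_equal(localAlignScore("ACGT", "ACGT"), 4L)
  expect_equal(localAlignScore("AAAATTTT", "AAAACTTTT"), 4L)
  expect_equal(localAlignScore("ACGTACGT", "TTTTTTTT"), 1L)
  expect_equal(affineSWOracle("AAAATTTT", "AAAACTTTT"), 4)
})

test_that("the DP kernel matches the brute-force affine oracle", {
  set.seed(301)
  params <- alignerParams()
  for (rep in 1:250) {
    ab <- c("A", "C", "G", "T", if (rep %% 5 == 0) "N")
    a <- randSeq(sample(5:40, 1), ab)
    b <- randSeq(sample(5:80, 1), ab)
    if (rep %% 3 == 0) {  # make some related pairs so high scores occur
      s <- sample(max(1, nchar(b) - nchar(a)), 1)
      b <- paste0(substr(b, 1, s), a, substr(b, s + 1, nchar(b)))
    }
    expect_equal(localAlignScore(a, b, params), affineSWOracle(a, b))
    tb <- localAlignTraceback(a, b, params)
    if (!is.null(tb)) {
      expect_equal(cigarScore(tb, a, b, params), tb$score)
      expect_lte(tb$refEnd - tb$refStart, 2L * nchar(a))
    }
  }
})

test_that("traceback reports soft clips, identity and coverage", {
  set.seed(302)
  window <- randSeq(160)
  read <- substr(window, 31, 130)  # perfect 100-mer
  tb <- localAlignTraceback(read, window)
  expect_equal(tb$cigar, "100M")
  expect_equal(tb$identity, 1.0)
  expect_equal(tb$coverage, 1.0)
  expect_equal(tb$refStart, 30L)

  ch <- strsplit(read, "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  tb2 <- localAlignTraceback(paste(ch, collapse = ""), window)
  expect_equal(tb2$cigar, "100M")
  expect_equal(tb2$identity, 99 / 100)

  tail4 <- paste0(substr(read, 1, 96), "NNNN")
  tb3 <- localAlignTraceback(tail4, window)
  expect_match(tb3$cigar, "4S$")
  expect_equal(tb3$coverage, 96 / 100)

  expect_null(localAlignTraceback("AAAA", "TTTT", alignerParams()))
})

test_that("region ranking filters and orders deterministically", {
  params <- alignerParams()
  d <- data.frame(start = c(10L, 40L, 5L), end = c(100L, 120L, 90L),
                  strand = "forward", score = c(45L, 28L, 60L))
  r <- rankRegions(d, params)
  expect_equal(r$score, c(60L, 45L))

  ties <- data.frame(start = c(50L, 10L), end = c(100L, 70L),
                     strand = "forward", score = c(40L, 40L))
  expect_equal(rankRegions(ties, params)$start, c(10L, 50L))
  expect_equal(nrow(rankRegions(d[0, ], params)), 0L)
})

test_that("single-end alignment recovers origin and filters junk", {
  set.seed(303)
  txt <- randSeq(20000)
  gi <- buildGenomeIndex(c(chr = txt))
  read <- substr(txt, 5001, 5200)
  aln <- alignReadSE(read, gi, name = "verbatim")
  expect_equal(aln$pos, 5001L)
  expect_equal(aln$cigar, "200M")
  expect_equal(aln$identity, 1.0)
  expect_equal(bitwAnd(aln$flag, 4L), 0L)

  rc <- alignReadSE(revCompChar(read), gi, name = "rc")
  expect_equal(rc$pos, 5001L)
  expect_equal(bitwAnd(rc$flag, 16L), 16L)

  # 25% corrupted read: identity filter rejects
  ch <- strsplit(read, "")[[1]]
  pick <- sample(200, 50)
  ch[pick] <- vapply(ch[pick],
                     function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
  bad <- alignReadSE(paste(ch, collapse = ""), gi, name = "noisy")
  expect_equal(bitwAnd(bad$flag, 4L), 4L)

  none <- alignReadSE(randSeq(200), gi, name = "absent")
  expect_equal(bitwAnd(none$flag, 4L), 4L)
})

test_that("candidate windows contain the true origin of simulated reads", {
  g <- smallGenome(); gi <- smallIndex()
  sim <- simulatePairs(g, 15, readLength = 120, errorRate = 0,
                       insertMean = 400, insertSd = 20, seed = 9)
  params <- alignerParams()
  for (i in seq_along(sim$reads1)) {
    cand <- memalign:::.seCandidates(sim$reads1[i], gi, params)
    x <- sim$truth$pos[i]
    hit <- any(cand$ranked$start <= x & cand$ranked$end >= x + 120 &
                 cand$ranked$strand == "forward")
    expect_true(hit)
  }
})
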