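# Seed-size estimation (binomial error model) and MEM generation.

test_that("maximal error estimate uses exact binomial tails", {
  expect_equal(estimateMaxErrors(100, 0.02, 0.04), 5L)
  expect_equal(estimateMaxErrors(200, 0.02, 0.04), 8L)
  expect_equal(estimateMaxErrors(500, 1e-12, 0.04), 0L)
  expect_equal(estimateMaxErrors(500, 0, 0.04), 0L)
  # strictness of P(w > z) < m at the documented boundary
  expect_gte(pbinom(4, 100, 0.02, lower.tail = FALSE), 0.04)
  expect_lt(pbinom(5, 100, 0.02, lower.tail = FALSE), 0.04)
})

test_that("minimal seed size reproduces the published values and clamps", {
  expect_equal(estimateMinSeedSize(100), 16L)
  expect_equal(estimateMinSeedSize(200), 22L)
  expect_equal(estimateMinSeedSize(30), 13L)    # floor(30/3) = 10, clamped up
  # upper clamp: at low error rates the pigeonhole size exceeds Q_H
  expect_equal(estimateMinSeedSize(100, alignerParams(errProb = 0.001)), 49L)
  # growth sanity: longer reads get larger seeds over doubling scales, with
  # local dips bounded by the error-count increments of the binomial bound
  lens <- 26:4000
  qs <- vapply(lens, estimateMinSeedSize, integer(1))
  expect_true(all(diff(qs) >= -3L))
  expect_true(all(diff(vapply(c(100, 400, 1600, 6400), estimateMinSeedSize,
                              integer(1))) > 0))
})

test_that("rescue seed size is the floored midpoint", {
  expect_equal(rescueSeedSize(22, 13), 17L)
  expect_equal(rescueSeedSize(13, 13), 13L)
  expect_equal(rescueSeedSize(16, 13), 14L)
  expect_error(rescueSeedSize(10, 13), "Q must be")
})

test_that("MEM scan reproduces the worked toy examples", {
  idx <- buildGenomeIndex(c(chr = "GATTACA"), u = 2L, v = 2L)
  s1 <- generateMEMs("TTAC", idx, Q = 3)
  expect_equal(s1[, c("readOffset", "genomePos", "length")],
               data.frame(readOffset = 0L, genomePos = 2L, length = 4L))
  s2 <- generateMEMs("GATA", idx, Q = 2)
  expect_equal(unname(as.matrix(s2[, 1:3])),
               matrix(c(0L, 0L, 3L, 2L, 3L, 2L), 2, byrow = TRUE))
  expect_equal(nrow(generateMEMs("CCCCCCC", idx, Q = 3)), 0L)
  expect_equal(nrow(generateMEMs("GA", idx, Q = 3)), 0L)  # shorter than Q
})

test_that("MEM scan matches the naive LEM reference on random pairs", {
  set.seed(201)
  for (rep in 1:12) {
    txt <- randSeq(sample(100:400, 1))
    gi <- buildGenomeIndex(c(chr = txt), u = 4L, v = 3L)
    # half the reads are genuine (noisy) genome substrings, half random
    if (rep %% 2 == 0) {
      s <- sample(nchar(txt) - 60, 1)
      read <- substr(txt, s, s + 59)
      ch <- strsplit(read, "")[[1]]
      for (k in sample(60, 3)) ch[k] <- sample(c("A", "C", "G", "T"), 1)
      read <- paste(ch, collapse = "")
    } else read <- randSeq(40)
    for (Q in c(3L, 6L)) {
      got <- generateMEMs(read, gi, Q = Q, h = 4096L)
      want <- naiveLEMScan(read, txt, Q)
      got <- got[order(got$readOffset, got$genomePos), ]
      expect_equal(got$readOffset, want$readOffset)
      expect_equal(got$genomePos, want$genomePos)
      expect_equal(got$length, want$length)
    }
  }
})

test_that("emitted seeds are true, right-maximal exact matches", {
  set.seed(202)
  txt <- randSeq(600)
  gi <- buildGenomeIndex(c(chr = txt), u = 8L, v = 4L)
  s <- sample(500, 1)
  read <- substr(txt, s, s + 79)
  seeds <- generateMEMs(read, gi, Q = 5)
  expect_gt(nrow(seeds), 0)
  for (i in seq_len(nrow(seeds))) {
    p <- seeds$readOffset[i]; g <- seeds$genomePos[i]; L <- seeds$length[i]
    expect_identical(substr(read, p + 1, p + L), substr(txt, g + 1, g + L))
    # right-maximal: next characters differ or a boundary is hit
    if (p + L < nchar(read) && g + L < nchar(txt))
      expect_false(substr(read, p + L + 1, p + L + 1) ==
                     substr(txt, g + L + 1, g + L + 1))
  }
})

test_that("occurrences per recorded LEM are capped at h", {
  rep40 <- paste(rep("ACGTT", 40), collapse = "")
  gi <- buildGenomeIndex(c(chr = rep40), u = 2L, v = 2L)
  seeds <- generateMEMs("ACGTTACGTT", gi, Q = 5, h = 7L)
  perLEM <- table(seeds$readOffset)
  expect_true(all(perLEM <= 7L))
  expect_gt(nrow(seeds), 0)
})

test_that("seeds never cross record boundaries or N positions", {
  gi <- buildGenomeIndex(c(a = "ACGTACGTAC", b = "GTACGTACGT"), u = 2L, v = 2L)
  seeds <- generateMEMs("ACGTACGTACGTACGTAC", gi, Q = 4, h = 4096L)
  off <- refOffsets(gi); len <- refLengths(gi)
  rec <- findInterval(seeds$genomePos, off)
  expect_true(all(seeds$genomePos + seeds$length <= off[rec] + len[rec]))

  gin <- buildGenomeIndex(c(chr = "ACGTACGTNNACGTACGT"), u = 2L, v = 2L)
  sn <- generateMEMs("ACGTACGTACGTACGT", gin, Q = 4, h = 4096L)
  if (nrow(sn) > 0) {
    nPos <- which(gin@reference@codes == 4L) - 1L
    for (i in seq_len(nrow(sn)))
      expect_false(any(nPos >= sn$genomePos[i] &
                         nPos < sn$genomePos[i] + sn$length[i]))
  }
})

test_that("seedsForRead searches both strands and rescues sparse reads", {
  set.seed(203)
  txt <- randSeq(10000)
  gi <- buildGenomeIndex(c(chr = txt))
  params <- alignerParams()

  # verbatim window: full-length seed at the standard Q
  read <- substr(txt, 2001, 2100)
  sf <- seedsForRead(read, gi, params)
  expect_equal(sf$usedQ, 16L)
  expect_true(any(sf$seeds$length == 100L & sf$seeds$strand == "forward"))

  # reverse-complement window maps to the reverse strand
  sfr <- seedsForRead(revCompChar(read), gi, params)
  expect_true(any(sfr$seeds$strand == "reverse"))

  # a read sharing only a 15-mer is found after rescue (Q = 16, Q_N = 14)
  repeat {
    rnd <- randSeq(100)
    probe <- seedsForRead(rnd, gi, params)
    if (nrow(probe$seeds) == 0 && probe$usedQ == 14L) break
  }
  pos <- 5001
  kmer <- substr(txt, pos, pos + 14)
  left <- setdiff(c("A", "C", "G", "T"), substr(txt, pos - 1, pos - 1))[1]
  right <- setdiff(c("A", "C", "G", "T"), substr(txt, pos + 15, pos + 15))[1]
  read15 <- paste0(substr(rnd, 1, 39), left, kmer, right, substr(rnd, 57, 100))
  sf15 <- seedsForRead(read15, gi, params)
  expect_equal(sf15$usedQ, 14L)
  expect_true(any(sf15$seeds$length == 15L))

  # random non-genomic read stays empty after rescue
  expect_equal(nrow(probe$seeds), 0L)
})
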