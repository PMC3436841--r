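# Index construction and substring search against naive oracles.

test_that("packReference concatenates records and flags Ns", {
  r1 <- packReference(c(chr = "GATTACA"))
  expect_equal(totalLength(r1), 7L)
  expect_equal(unname(refOffsets(r1)), 0L)

  r2 <- packReference(c(a = "ACGT", b = "GGGG"))
  expect_equal(unname(refOffsets(r2)), c(0L, 4L))
  expect_equal(totalLength(r2), 8L)

  r3 <- packReference(c(x = "ACNNG"))
  expect_equal(which(r3@codes == 4L) - 1L, c(2L, 3L))

  expect_error(packReference(character(0)), "no reference")
  expect_error(packReference(c(bad = "ACXGT")), "illegal character 'X'.*offset 2")
})

test_that("suffix array matches enumeration and is sorted", {
  expect_equal(buildSuffixArray("GATTACA"), c(7L, 6L, 4L, 1L, 5L, 0L, 3L, 2L))
  expect_equal(buildSuffixArray("AAA"), c(3L, 2L, 1L, 0L))

  set.seed(101)
  for (rep in 1:5) {
    txt <- randSeq(sample(50:300, 1))
    sa <- buildSuffixArray(txt)
    withDollar <- paste0(txt, "!")  # '!' < ACGT, stands in for the terminator
    sufs <- substring(withDollar, sa + 1L, nchar(withDollar))
    expect_false(is.unsorted(sufs, strictly = TRUE))
  }
})

test_that("BWT is the last rotation column and a permutation of text plus $", {
  expect_equal(bwtFromSuffixArray("GATTACA", buildSuffixArray("GATTACA")),
               "ACTGA$TA")
  expect_equal(bwtFromSuffixArray("A", buildSuffixArray("A")), "A$")
  set.seed(102)
  txt <- randSeq(120)
  b <- bwtFromSuffixArray(txt, buildSuffixArray(txt))
  expect_equal(sort(strsplit(b, "")[[1]]),
               sort(strsplit(paste0(txt, "$"), "")[[1]]))
})

test_that("occ queries equal direct counts for every base and position", {
  set.seed(103)
  txt <- randSeq(200)
  bwt <- bwtFromSuffixArray(txt, buildSuffixArray(txt))
  chars <- strsplit(bwt, "")[[1]]
  for (u in c(1L, 7L, 128L)) {
    fm <- buildFMIndex(bwt, u = u)
    for (a in c("A", "C", "G", "T")) {
      direct <- cumsum(chars == a)
      idx <- sort(sample(seq_along(chars), 40))
      for (i in idx) expect_equal(occCount(fm, a, i - 1L), direct[i])
    }
    expect_equal(occCount(fm, "A", -1L), 0L)
  }
})

test_that("backward search and locate reproduce the naive substring scan", {
  idx <- buildGenomeIndex(c(chr = "GATTACA"), u = 3L, v = 2L)
  expect_equal(width(backwardSearch(idx, "A")), 3L)
  expect_equal(width(backwardSearch(idx, "TA")), 1L)
  expect_equal(width(backwardSearch(idx, "TTT")), 0L)
  expect_equal(sort(locateOccurrences(idx, interval = backwardSearch(idx, "A"))),
               c(1L, 4L, 6L))
  expect_equal(locateOccurrences(idx, interval = backwardSearch(idx, "GATTACA"))
               , 0L)

  set.seed(104)
  for (rep in 1:3) {
    txt <- randSeq(sample(80:300, 1))
    gi <- buildGenomeIndex(c(chr = txt), u = 4L, v = 3L)
    for (L in 1:12) {
      starts <- sample(seq_len(nchar(txt) - L + 1L), min(10, nchar(txt) - L + 1L))
      for (s in starts) {
        pat <- substr(txt, s, s + L - 1L)
        truth <- naiveOccurrences(txt, pat)
        iv <- backwardSearch(gi, pat)
        expect_equal(width(iv), length(truth))
        expect_equal(sort(locateOccurrences(gi, interval = iv, limit = 4096L)),
                     truth)
      }
    }
    absent <- paste0(substr(txt, 1, 6), "NACGT")
    expect_equal(width(backwardSearch(gi, absent)), 0L)
  }
})

test_that("locate respects the limit and subset contract", {
  idx <- buildGenomeIndex(c(chr = "GATTACA"), v = 2L)
  iv <- backwardSearch(idx, "A")
  two <- locateOccurrences(idx, interval = iv, limit = 2L)
  expect_length(two, 2L)
  expect_true(all(two %in% c(1L, 4L, 6L)))
  expect_error(locateOccurrences(idx, interval = iv, limit = 0L), "limit")
})

test_that("answers are independent of the sampling factors u and v", {
  set.seed(105)
  txt <- randSeq(250)
  pats <- vapply(1:15, function(i) {
    s <- sample(240, 1); substr(txt, s, s + sample(3:9, 1))
  }, character(1))
  base <- buildGenomeIndex(c(chr = txt), u = 1L, v = 1L)
  for (u in c(5L, 64L, 128L)) for (v in c(2L, 8L, 16L)) {
    gi <- buildGenomeIndex(c(chr = txt), u = u, v = v)
    for (p in pats) {
      ivb <- backwardSearch(base, p); iv <- backwardSearch(gi, p)
      expect_equal(c(iv@lo, iv@hi), c(ivb@lo, ivb@hi))
      expect_equal(sort(locateOccurrences(gi, interval = iv)),
                   sort(locateOccurrences(base, interval = ivb)))
    }
  }
})

test_that("degenerate sampling factors behave as the full structures", {
  set.seed(106)
  txt <- randSeq(90)
  sa <- buildSuffixArray(txt)
  ssa <- buildSampledSA(sa, v = 1L)
  expect_equal(sort(ssa@values), sort(sa))  # every position retained
  bwt <- bwtFromSuffixArray(txt, sa)
  fm1 <- buildFMIndex(bwt, u = 1L)
  expect_equal(ncol(fm1@occCheckpoints), nchar(txt) + 2L)
  expect_error(buildFMIndex(bwt, u = 0L), "u must be")
  expect_error(buildSampledSA(sa, v = 0L), "v must be")
})

test_that("the text is recoverable from the BWT by LF mapping", {
  set.seed(107)
  for (n in c(1, 37, 160)) {
    txt <- randSeq(n)
    idx <- buildGenomeIndex(c(chr = txt), u = 5L, v = 3L)
    expect_equal(memalign:::.reconstructText(idx@fwd), txt)
  }
})

test_that("memory formulas reproduce the closed forms and are monotone", {
  gb <- function(bits) bits / 8 / 1e9
  expect_equal(predictIndexMemory(256, 1, 1, "full_sa"), 2048)
  expect_equal(gb(predictIndexMemory(3e9, variant = "full_sa")), 12)
  expect_equal(gb(predictIndexMemory(3e9, 128, 8, "reduced_total")), 2.625)
  for (v in c("full_sa", "full_index", "reduced_fm", "reduced_sa",
              "reduced_total")) {
    sizes <- vapply(c(1e3, 1e5, 1e7, 3e9, 1e10), predictIndexMemory,
                    numeric(1), u = 128, v = 8, variant = v)
    expect_false(is.unsorted(sizes))
  }
  expect_error(predictIndexMemory(1), "totalLength")
})
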