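# Shared fixtures, built once per test run on first use. The desk-scale study
# condition: a 1-Mbp seeded random genome standing in for a large reference,
# 2,000 simulated 200-bp pairs at 2% uniform error (10% of errors indels),
# insert sizes N(1000, 50).

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, build(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

deskGenome <- function() .cached("genome", function() {
  simulateGenome(1000000L, seed = 42)
})

deskIndex <- function() .cached("index", function() {
  buildGenomeIndex(deskGenome())
})

deskSim <- function() .cached("sim", function() {
  simulatePairs(deskGenome(), 2000L, readLength = 200L, errorRate = 0.02,
                indelFraction = 0.10, insertMean = 1000, insertSd = 50,
                seed = 43)
})

deskAlignSE <- function() .cached("se", function() {
  sim <- deskSim()
  alignReads(deskIndex(), c(sim$reads1, sim$reads2),
             names = c(paste0(sim$names, "/1"), paste0(sim$names, "/2")))
})

deskAlignPE <- function() .cached("pe", function() {
  sim <- deskSim()
  alignReads(deskIndex(), sim$reads1, sim$reads2, names = sim$names)
})

# small fixtures for the paired-end unit tests
smallGenome <- function() .cached("smallGenome", function() {
  simulateGenome(100000L, seed = 7)
})

smallIndex <- function() .cached("smallIndex", function() {
  buildGenomeIndex(smallGenome())
})
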