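# Shared fixtures: built in code at test time.

# near-normal insert-size histogram
makeNormalHist <- function(n = 20000, mean = 450, sd = 15, seed = 42,
                           readGroup = 1L) {
  set.seed(seed)
  newInsertSizeHistogram(pmax(round(rnorm(n, mean, sd)), 1), readGroup)
}

# WindowHistogram with explicit probabilities at chosen deviations
makeWindowHist <- function(deltas, probs, floor = 1e-10) {
  dmin <- min(deltas)
  p <- rep(floor, max(deltas) - dmin + 1L)
  p[deltas - dmin + 1L] <- probs
  new("WindowHistogram", probs = p, deltaMin = as.integer(dmin),
      floor = floor)
}

# random sorted record set on a small dictionary
randomRecords <- function(n, seed, nContigs = 2L, nGroups = 1L,
                          contigLen = 200000L) {
  set.seed(seed)
  r <- data.frame(
    contig = sample.int(nContigs, n, replace = TRUE),
    fwdStart = sample.int(contigLen - 1000L, n, replace = TRUE) - 1L,
    insertSize = pmax(round(rnorm(n, 450, 15)), 1L),
    readGroup = sample.int(nGroups, n, replace = TRUE))
  r <- r[order(r$contig, r$fwdStart), , drop = FALSE]
  rownames(r) <- NULL
  r
}

randomProfile <- function(seed, n = 5000L, nContigs = 2L, nGroups = 1L) {
  recs <- randomRecords(n, seed, nContigs, nGroups)
  sl <- setNames(rep(200000L, nContigs), paste0("ctg", seq_len(nContigs)))
  cfg <- jdConfig(minSamplePairs = 100L)
  buildProfile(recs, sl, paste0("s", seed), config = cfg)
}

# small cohort used by several end-to-end style tests
tinyCohortFixture <- function(seed = 7L, nSamples = 6L, nDel = 5L,
                              contigLen = 400000L,
                              lenRange = c(600, 3000)) {
  dels <- simulateDeletionSet(nDel, contigLen, lenRange = lenRange,
                              seed = seed)
  coh <- simulateGenotypes(dels, nSamples, seed = seed + 1L)
  profs <- simulateCohortProfiles(coh, coverage = 30, seed = seed + 2L)
  list(dels = dels, coh = coh, profs = profs)
}
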