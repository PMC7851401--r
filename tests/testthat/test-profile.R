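# Profiling: insert-size arithmetic, quality filters, null estimation.

test_that("insert size is the clip-extended forward-to-reverse distance", {
  expect_identical(computeInsertSize(1000, 1300), 300L)
  expect_identical(computeInsertSize(1000, 1300, fwdLeftClip = 5,
                                     revRightClip = 10), 315L)
  expect_true(is.na(computeInsertSize(0, 0)))
  expect_true(is.na(computeInsertSize(500, 400)))
})

test_that("insert size is translation invariant", {
  set.seed(1)
  for (i in 1:20) {
    s <- sample.int(1e6, 1)
    e <- s + sample.int(1000, 1)
    k <- sample(-1e5:1e5, 1)
    expect_identical(computeInsertSize(s, e), computeInsertSize(s + k, e + k))
  }
})

test_that("quality filter keeps primary FR pairs above the MAPQ threshold", {
  cfg <- jdConfig()
  # flags: 99 = paired, proper, mate reverse, first in pair (forward read)
  expect_true(passesQualityFilters(list(flag = 99L, mapq = 60L), cfg))
  expect_false(passesQualityFilters(list(flag = 99L + 1024L, mapq = 60L), cfg))   # duplicate
  expect_false(passesQualityFilters(list(flag = 99L, mapq = 10L), cfg))           # low MAPQ
  expect_false(passesQualityFilters(list(flag = 99L + 256L, mapq = 60L), cfg))    # secondary
  expect_false(passesQualityFilters(list(flag = 99L + 2048L, mapq = 60L), cfg))   # supplementary
  expect_false(passesQualityFilters(list(flag = 77L, mapq = 60L), cfg))           # both unmapped
  expect_false(passesQualityFilters(                                              # cross-contig
    list(flag = 99L, mapq = 60L, rname = "c1", mrnm = "c2"), cfg))
  # same-strand pair is not FR-compatible
  expect_false(passesQualityFilters(list(flag = 67L, mapq = 60L), cfg))
})

test_that("null distribution estimation recovers generating parameters", {
  cfg <- jdConfig(minSamplePairs = 100L)
  sl <- c(ctg1 = 100000L)
  # degenerate stream: all inserts 300
  recs <- data.frame(contig = 1L, fwdStart = sort(sample.int(90000L, 2000L)) - 1L,
                     insertSize = 300L, readGroup = 1L)
  h <- estimateNullDistribution(recs, sl, config = cfg)[["1"]]
  expect_equal(h@mean, 300)
  expect_equal(h@sd, 0)
  expect_equal(h@total, sum(recs$fwdStart >= 20000 & recs$fwdStart < 80000))

  set.seed(99)
  recs <- data.frame(contig = 1L,
                     fwdStart = sort(sample.int(90000L, 10000L, TRUE)) - 1L,
                     insertSize = pmax(round(rnorm(10000, 450, 15)), 1L),
                     readGroup = 1L)
  regions <- data.frame(contig = "ctg1", start = 0L, end = 100000L)
  h <- estimateNullDistribution(recs, sl, regions, cfg)[["1"]]
  expect_lt(abs(h@mean - 450), 1)
  expect_lt(abs(h@sd - 15), 0.5)

  # no records inside the sampling regions
  far <- data.frame(contig = "ctg1", start = 95000L, end = 96000L)
  expect_error(estimateNullDistribution(recs[recs$fwdStart < 90000, ], sl,
                                        far, cfg),
               "insufficient data")
  expect_error(estimateNullDistribution(recs, sl,
                                        data.frame(contig = character(),
                                                   start = integer(),
                                                   end = integer()), cfg),
               "empty")
  expect_error(estimateNullDistribution(recs, sl,
                                        data.frame(contig = "nope",
                                                   start = 0L, end = 10L),
                                        cfg),
               "absent from the sequence dictionary")
})

test_that("null estimation is permutation invariant in record order", {
  cfg <- jdConfig(minSamplePairs = 100L)
  sl <- c(ctg1 = 100000L)
  set.seed(5)
  recs <- randomRecords(3000L, 5, nContigs = 1L, contigLen = 100000L)
  h1 <- estimateNullDistribution(recs, sl, config = cfg)[["1"]]
  h2 <- estimateNullDistribution(recs[sample.int(nrow(recs)), ], sl,
                                 config = cfg)[["1"]]
  expect_equal(h1@counts, h2@counts)
  expect_equal(h1@mean, h2@mean)
})

test_that("profile round trip through the binary format is lossless", {
  for (seed in c(1, 2, 3)) {
    p <- randomProfile(seed, nGroups = if (seed == 3) 2L else 1L)
    f <- tempfile(fileext = ".jdp")
    writeProfile(p, f)
    q <- readProfile(f)
    expect_identical(sampleId(q), sampleId(p))
    expect_identical(seqDict(q), seqDict(p))
    expect_equal(profileRecords(q), profileRecords(p))
    expect_equal(length(histograms(q)), length(histograms(p)))
    for (g in names(histograms(p))) {
      expect_equal(histograms(q)[[g]]@counts, histograms(p)[[g]]@counts)
      expect_equal(histograms(q)[[g]]@mean, histograms(p)[[g]]@mean)
      expect_equal(histograms(q)[[g]]@sd, histograms(p)[[g]]@sd)
    }
    unlink(f)
  }
})

test_that("profile seek returns exactly the records at or after a position", {
  p <- randomProfile(11)
  f <- tempfile(fileext = ".jdp")
  writeProfile(p, f)
  r <- profileRecords(p)
  for (pos in c(0L, 1L, 70000L, 150000L)) {
    got <- profileSeek(f, "ctg1", pos)
    want <- r[r$contig == 1L & r$fwdStart >= pos, , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("pos", pos))
  }
  # past the last record: empty
  expect_equal(nrow(profileSeek(f, "ctg1", 300000L)), 0L)
  expect_error(profileSeek(f, "chrNope", 0L), "not in profile")
  unlink(f)
})

test_that("profile files fail loudly on bad magic or truncation", {
  p <- randomProfile(21)
  f <- tempfile(fileext = ".jdp")
  writeProfile(p, f)
  raw <- readBin(f, "raw", file.size(f))
  bad <- tempfile()
  writeBin(c(charToRaw("XXXX"), raw[-(1:4)]), bad)
  expect_error(readProfile(bad), "magic")
  trunc <- tempfile()
  writeBin(raw[1:(length(raw) %/% 2)], trunc)
  expect_error(readProfile(trunc), "truncat|corrupt")
  unlink(c(f, bad, trunc))
})

test_that("a profile is far smaller than the equivalent SAM rendering", {
  dels <- simulateDeletionSet(3, 1e6, lenRange = c(600, 2000), seed = 31)
  coh <- simulateGenotypes(dels, 1, seed = 32)
  recs <- simulateReadPairs(coh, coverage = 30, seed = 33)[[1]]
  sl <- c(chrS = 1000000L)
  prof <- buildProfile(recs, sl, "s1", config = jdConfig())
  jdp <- tempfile(fileext = ".jdp")
  sam <- tempfile(fileext = ".sam")
  writeProfile(prof, jdp)
  writeSam(recs, sl, sam)
  expect_lt(file.size(jdp) / file.size(sam), 0.05)
  unlink(c(jdp, sam))
})

test_that("BAM ingestion reproduces the simulated pairs, clip-extended", {
  dels <- simulateDeletionSet(2, 2e5, lenRange = c(600, 1200), seed = 41)
  coh <- simulateGenotypes(dels, 1, seed = 42)
  recs <- simulateReadPairs(coh, coverage = 10, seed = 43)[[1]]
  sl <- c(chrS = 200000L)
  sam <- tempfile(fileext = ".sam")
  writeSam(recs, sl, sam)
  prof <- profileBam(sam, sampleId = "bam1",
                     config = jdConfig(minSamplePairs = 100L))
  got <- profileRecords(prof)
  expect_identical(nrow(got), nrow(recs))
  og <- order(got$fwdStart, got$insertSize)
  orc <- order(recs$fwdStart, recs$insertSize)
  expect_equal(got$fwdStart[og], recs$fwdStart[orc])
  expect_equal(got$insertSize[og], recs$insertSize[orc])
  unlink(sam)
})

test_that("clipped alignments extend the insert size on ingestion", {
  # hand-crafted pair: fwd at POS 1001 with 5 bp left soft clip,
  # rev ending at 1300 (0-based exclusive) with 10 bp right soft clip
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ctg1\tLN:100000",
    paste("q1", 99, "ctg1", 1001, 60, "5S95M", "=", 1206, 300,
          strrep("N", 100), "*", sep = "\t"),
    paste("q1", 147, "ctg1", 1206, 60, "85M10S", "=", 1001, -300,
          strrep("N", 95), "*", sep = "\t")), sam)
  cfg <- jdConfig(minSamplePairs = 1L)
  prof <- profileBam(sam, samplingRegions = data.frame(
    contig = "ctg1", start = 0L, end = 100000L), config = cfg)
  r <- profileRecords(prof)
  expect_identical(nrow(r), 1L)
  # (1290 + 10) - (1000 - 5) = 305
  expect_identical(r$insertSize, 305L)
  expect_identical(r$fwdStart, 1000L)
  unlink(sam)
})

test_that("non-coordinate-sorted input is rejected", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:queryname",
    "@SQ\tSN:ctg1\tLN:100000",
    paste("q1", 99, "ctg1", 1001, 60, "100M", "=", 1201, 300,
          strrep("N", 100), "*", sep = "\t"),
    paste("q1", 147, "ctg1", 1201, 60, "100M", "=", 1001, -300,
          strrep("N", 100), "*", sep = "\t")), sam)
  expect_error(profileBam(sam), "coordinate-sorted")
  expect_error(profileBam(tempfile()), "no such file")
  unlink(sam)
})
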