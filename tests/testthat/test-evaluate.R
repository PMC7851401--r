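# Call-set matching, filtering, HWE, trio statistics, matrix export.

test_that("reciprocal overlap is the minimum mutual fraction", {
  expect_equal(reciprocalOverlap(100, 200, 150, 250), 0.5)
  expect_equal(reciprocalOverlap(100, 200, 100, 200), 1)
  expect_equal(reciprocalOverlap(100, 200, 300, 400), 0)
  # containment: short interval fully inside a long one
  expect_equal(reciprocalOverlap(0, 1000, 400, 500), 0.1)
  expect_equal(reciprocalOverlap(0, 100, 50, 150,
                                 aContig = "c1", bContig = "c2"), 0)
})

test_that("call-truth matching is one-to-one at 50 percent overlap", {
  truth <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = c(1001, 5001), width = c(1000, 2000)))
  # identical sets
  m <- matchCallsets(truth, truth)
  expect_equal(m$recall, 1); expect_equal(m$precision, 1)
  expect_equal(m$f1, 1)

  # two calls both overlapping one truth: one TP, one FP
  calls2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = c(1001, 1101), width = c(1000, 1000)))
  m2 <- matchCallsets(calls2, truth[1])
  expect_identical(m2$nTP, 1L)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  # the better-overlapping call wins deterministically
  expect_identical(m2$matches$call, 1L)

  # 49 percent reciprocal overlap: a miss and a false positive
  call49 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1511, width = 1000))
  m3 <- matchCallsets(call49, truth[1])
  expect_identical(m3$nTP, 0L)
  expect_equal(m3$recall, 0)
  # at exactly 50 percent the pair matches
  call50 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1501, width = 1000))
  expect_identical(matchCallsets(call50, truth[1])$nTP, 1L)
})

test_that("size, region and GQ filters act as documented", {
  dels <- simulateDeletionSet(40, 4e6, lenRange = c(300, 12000), seed = 81)
  coh <- simulateGenotypes(dels, 4, seed = 82)
  cs <- writeTruth(coh)
  w <- GenomicRanges::width(calls(cs))

  kept <- filterCalls(cs, sizeMin = 500, sizeMax = 10000)
  expect_identical(length(calls(kept)), sum(w >= 500 & w <= 10000))

  # any overlap with an excluded region removes the call (even 1 bp)
  g1 <- calls(cs)[1]
  ex <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g1),
    IRanges::IRanges(GenomicRanges::start(g1) - 5,
                     GenomicRanges::start(g1)))
  kept2 <- filterCalls(cs, sizeMin = 0, sizeMax = Inf, excludeBed = ex)
  expect_identical(length(calls(kept2)), length(calls(cs)) - 1L)

  # empty filters are the identity
  kept3 <- filterCalls(cs, sizeMin = 0, sizeMax = Inf)
  expect_identical(genotypes(kept3), genotypes(cs))

  # GQ masking
  cs@GQ[1, 1] <- 5L
  kept4 <- filterCalls(cs, sizeMin = 0, sizeMax = Inf, gqMin = 20)
  expect_identical(unname(genotypes(kept4)[1, 1]), "./.")
})

test_that("malformed BED files fail with a line number", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\tx\t300"), bad)
  expect_error(readBed(bad), "line 2")
  writeLines(c("chr1\t100"), bad)
  expect_error(readBed(bad), "line 1")
  unlink(bad)
})

test_that("exact HWE test matches brute-force enumeration for small n", {
  for (cnt in list(c(2, 2, 1), c(1, 4, 0), c(3, 0, 2), c(4, 1, 0),
                   c(0, 5, 0), c(2, 0, 2))) {
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 oracleHweExact(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-9,
                 info = paste(cnt, collapse = "/"))
  }
})

test_that("HWE filter keeps equilibrium sites and drops het deficits", {
  expect_true(hweFilter(matrix(c(25, 50, 25), 1))[1])
  expect_false(hweFilter(matrix(c(50, 0, 50), 1))[1])
  # monomorphic sites are kept with P = 1
  expect_equal(hweExactTest(30, 0, 0), 1)
  expect_true(hweFilter(matrix(c(30, 0, 0), 1))[1])
  expect_equal(hweExactTest(0, 0, 30), 1)
})

test_that("Mendelian classification is exhaustive and parent-symmetric", {
  for (fa in 0:2) for (mo in 0:2) for (ch in 0:2) {
    got <- mendelianConsistent(fa, mo, ch)
    expect_identical(got, oracleMendelOk(fa, mo, ch),
                     info = sprintf("%d x %d -> %d", fa, mo, ch))
    expect_identical(got, mendelianConsistent(mo, fa, ch))
  }
})

test_that("error rate counts errors among non-ignored trios", {
  tab <- data.frame(
    site = c(1, 1, 2, 3, 4),
    trio = c(1, 2, 1, 1, 1),
    father = c(0L, 0L, 1L, 0L, NA),
    mother = c(0L, 1L, 2L, 0L, 0L),
    child  = c(1L, 1L, 0L, 0L, 1L),   # err, ok, err, all-ref, missing
    fatherGQ = 99L, motherGQ = 99L, childGQ = 99L)
  res <- mendelianErrorRate(tab)
  expect_identical(res$nErrors, 2L)
  expect_identical(res$nConsistent, 1L)
  expect_equal(res$errorRate, 2 / 3)
})

test_that("transmission rate reproduces the counting rules", {
  # unique-to-one-trio sites with parents {0/1, 0/0}: transmitted iff the
  # child is 0/1
  nUn <- 1714L; nTr <- 1680L
  tab <- data.frame(
    site = seq_len(nUn + nTr),
    trio = 1L,
    father = 1L, mother = 0L,
    child = c(rep(0L, nUn), rep(1L, nTr)),
    fatherGQ = 99L, motherGQ = 99L, childGQ = 99L)
  res <- transmissionRate(tab, mode = "unique_single_parent")
  expect_identical(res$considered, nUn + nTr)
  expect_identical(res$transmitted, nTr)
  expect_equal(round(res$rate, 2), 49.50)

  # sites shared by two trios are not considered in that mode
  tab2 <- rbind(tab[1:2, ], transform(tab[1:2, ], trio = 2L))
  expect_identical(transmissionRate(tab2, "unique_single_parent")$considered, 0L)

  # all transmitted
  tabAll <- transform(tab, child = 1L)
  expect_equal(transmissionRate(tabAll, "unique_single_parent")$rate, 100)

  # "all" mode: each het parent is one opportunity
  tab3 <- data.frame(
    site = 1:3, trio = 1L,
    father = c(1L, 1L, 2L), mother = c(1L, 0L, 1L),
    child = c(1L, 1L, 2L),
    fatherGQ = 99L, motherGQ = 99L, childGQ = 99L)
  res3 <- transmissionRate(tab3, mode = "all")
  # site1: 2 opportunities, 1 transmitted; site2: 1 opp, 1 transmitted;
  # site3: 1 opp (mother), child 2 - forced 1 = 1 transmitted
  expect_identical(res3$considered, 4L)
  expect_identical(res3$transmitted, 3L)
})

test_that("simulated Mendelian trios give zero errors and ~50% transmission", {
  dels <- simulateDeletionSet(400, 8e6, seed = 91)
  tab <- simulateTrios(dels, nTrios = 40, seed = 92)
  res <- mendelianErrorRate(tab)
  expect_identical(res$nErrors, 0L)
  tr <- transmissionRate(tab, mode = "all")
  ciHalf <- 1.96 * 50 / sqrt(tr$considered)
  expect_lt(abs(tr$rate - 50), ciHalf * 1.5)
})

test_that("de novo candidates require carrier child, 0/0 parents, high GQ", {
  tab <- data.frame(
    site = 1:5, trio = 1L,
    father = c(0L, 0L, 1L, 0L, 0L),
    mother = c(0L, 0L, 0L, 0L, 0L),
    child  = c(1L, 1L, 1L, 2L, 0L),
    fatherGQ = c(60L, 60L, 60L, 60L, 60L),
    motherGQ = c(60L, 60L, 60L, 60L, 60L),
    childGQ  = c(60L, 30L, 60L, 60L, 60L))
  cand <- deNovoCandidates(tab, gqMin = 50)
  expect_identical(cand$site, c(1L, 4L))
})

test_that("expected de novo counts scale the verified reference rate", {
  expect_equal(expectedDeNovo(7, 258, 49), 1.33)
  expect_equal(expectedDeNovo(0, 258, 100), 0)
  expect_equal(expectedDeNovo(7, 258, 258), 7)
})

test_that("genotype matrix export drops monomorphic sites", {
  dels <- simulateDeletionSet(10, 2e6, seed = 95)
  coh <- simulateGenotypes(dels, 6, seed = 96)
  cs <- writeTruth(coh)
  m <- genotypeMatrix(cs)
  g <- genotypes(coh)
  poly <- apply(g, 2, function(x) length(unique(x)) > 1L)
  expect_identical(dim(m), c(6L, sum(poly)))
  expect_identical(unname(m[, 1]), unname(g[, which(poly)[1]]))
  # a fully reference site would be dropped
  gt <- genotypes(cs)
  gt[1, ] <- "0/0"
  cs@GT <- gt
  expect_lte(ncol(genotypeMatrix(cs)), ncol(m))
})
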