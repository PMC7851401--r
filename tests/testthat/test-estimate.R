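# Iterative estimation: initialisation, update equations, convergence.

test_that("length initialisation clusters similar third quartiles", {
  # constant deviation vectors have their value as third quartile
  dl <- list(rep(500, 8), rep(505, 8), rep(2000, 8))
  inits <- initializeLengths(dl, nullSd = c(10, 10, 10), minLen = 100)
  expect_equal(sort(inits), c(502.5, 2000))

  # all deviations near zero: nothing above the minimum length
  expect_equal(initializeLengths(list(rnorm(10, 0, 3)), 10, minLen = 100),
               numeric())

  # single sample: its own quartile
  expect_equal(initializeLengths(list(rep(750, 4)), 10, minLen = 100), 750)

  # clustering gap is max(pooled sd, 40): distant quartiles stay separate
  dl2 <- list(rep(500, 4), rep(560, 4))
  expect_equal(sort(initializeLengths(dl2, c(10, 10), minLen = 100)),
               c(500, 560))
  # with a large pooled sd they merge
  expect_equal(initializeLengths(dl2, c(80, 80), minLen = 100), 530)
})

test_that("initial allele frequency is the supporting-pair fraction", {
  sd <- 15
  delta <- c(rep(0, 45), rep(800, 5))          # 5 of 50 supporting
  expect_equal(initializeAlleleFrequency(delta, sd, nSamples = 10), 0.1)
  # clamped at 1/(2 n) from below ...
  expect_equal(initializeAlleleFrequency(rep(0, 100), sd, nSamples = 100),
               1 / 200)
  # ... and 1 - 1/(2 n) from above
  expect_equal(initializeAlleleFrequency(rep(900, 10), sd, nSamples = 4),
               1 - 1 / 8)
  expect_true(is.na(initializeAlleleFrequency(numeric(), sd, 10)))
})

test_that("allele-frequency update averages expected allele counts", {
  W <- rbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(updateAlleleFrequency(W), 0.75)
  expect_equal(updateAlleleFrequency(rbind(c(1, 0, 0), c(1, 0, 0))), 0)
  expect_equal(updateAlleleFrequency(rbind(c(0, 0, 1), c(0, 0, 1))), 1)
  set.seed(4)
  for (i in 1:10) {
    W <- t(apply(matrix(runif(9), 3), 1, function(x) x / sum(x)))
    f <- updateAlleleFrequency(W)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(f, oracleUpdateF(split(W, row(W))[c("1", "2", "3")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("shift probabilities interpolate between genotype weights", {
  wh <- makeWindowHist(c(0L, 500L), c(0.2, 0.2))
  expect_equal(shiftProbability(0, wh, l = 500, a1 = 0, a2 = 1), 1)
  # H(delta - l) = H(delta - eps): a1 = 1, a2 = 0 gives exactly 1/2
  expect_equal(shiftProbability(250, wh, l = 500, a1 = 1, a2 = 0), 0.5)
  # constructed H(delta - l) = 3 * H(delta - eps)
  wh2 <- makeWindowHist(c(0L, 500L), c(0.3, 0.1))
  expect_equal(shiftProbability(500, wh2, l = 500, a1 = 0.5, a2 = 0.25),
               0.5 * 0.75 + 0.25)
})

test_that("length update is the P-weighted mean deviation", {
  expect_equal(updateLength(c(490, 500, 510), c(1, 1, 1)), 500)
  expect_equal(updateLength(c(0, 0, 750), c(0, 0, 1)), 750)
  expect_equal(updateLength(c(0, 1000), c(0, 1)), 1000)
  expect_true(is.na(updateLength(c(1, 2), c(0, 0))))
  set.seed(9)
  for (i in 1:10) {
    d <- rnorm(20, 500, 50)
    P <- runif(20)
    l <- updateLength(d, P)
    expect_gte(l, min(d)); expect_lte(l, max(d))
  }
})

test_that("noise-free data at the true parameters converge immediately", {
  # zero-variance inserts: H concentrated at 0; carriers' deviations are
  # exactly l
  lStar <- 800
  wh <- makeWindowHist(c(0L), c(1))
  genotype <- c(2L, 1L, 0L, 0L)             # realized allele freq 3/8
  deltaList <- lapply(genotype, function(g)
    c(rep(lStar, 5L * g), rep(0, 5L * (2L - g))))
  st <- iterateWindow(deltaList, wh, lInit = lStar, fInit = 0.3,
                      minLen = 100)
  expect_true(st$converged)
  expect_equal(st$l, lStar, tolerance = 1e-6)
  expect_equal(st$f, 3 / 8, tolerance = 1e-3)
  expect_lte(st$iterations, 2L)
  expect_true(st$reject)
  # genotype posteriors identify carriers
  expect_equal(apply(st$logLik, 1, which.max) - 1L, genotype)
})

test_that("windows without deviations give no call", {
  wh <- makeWindowHist(c(-5L, 0L, 5L), c(0.2, 0.4, 0.2))
  st <- iterateWindow(list(rep(0, 10), rep(0, 10)), wh,
                      lInit = 500, fInit = 0.2, minLen = 100)
  expect_identical(st$status, "nocall")
  expect_identical(
    estimateWindow(list(rnorm(10, 0, 3)), wh, nullSd = 15,
                   minLen = 100), list())
})

test_that("two deletion lengths in one window give two initialisations", {
  set.seed(77)
  hist <- makeNormalHist(seed = 78)
  wh <- transformHistogram(hist, 30L)
  deltaList <- list(round(rnorm(40, 500, 15)),    # hom carrier of 500
                    round(rnorm(40, 5000, 15)),   # hom carrier of 5000
                    round(rnorm(40, 0, 15)))
  states <- estimateWindow(deltaList, list(wh, wh, wh), nullSd = 15,
                           minLen = 50)
  expect_gte(length(states), 2L)
  ls <- sort(vapply(states, `[[`, 1, "l"))
  expect_lt(abs(ls[1] - 500), 30)
  expect_lt(abs(ls[length(ls)] - 5000), 30)
})

test_that("simulated windows recover length and frequency", {
  set.seed(101)
  hist <- makeNormalHist(seed = 102)
  wh <- transformHistogram(hist, 30L)
  nWin <- 20L
  errL <- errF <- numeric(nWin)
  for (i in seq_len(nWin)) {
    lStar <- runif(1, 500, 10000)
    fStar <- runif(1, 0.05, 0.95)
    sim <- simulateWindow(lStar, fStar, nSamples = 40, insertSd = 15,
                          seed = 200 + i)
    states <- estimateWindow(sim$deltaList, wh, nullSd = 15, minLen = 50)
    expect_gt(length(states), 0L)
    best <- states[[which.max(vapply(states, `[[`, 1, "stat"))]]
    errL[i] <- abs(best$l - lStar)
    errF[i] <- abs(best$f - fStar)
  }
  expect_lte(median(errL), 2 * 15)
  expect_lte(median(errF), 0.06)
})

test_that("estimation is invariant under sample permutation", {
  set.seed(55)
  hist <- makeNormalHist(seed = 56)
  wh <- transformHistogram(hist, 30L)
  sim <- simulateWindow(1200, 0.4, nSamples = 12, seed = 57)
  st <- estimateWindow(sim$deltaList, wh, nullSd = 15, minLen = 50)[[1]]
  perm <- sample(length(sim$deltaList))
  stP <- estimateWindow(sim$deltaList[perm], wh, nullSd = 15, minLen = 50)[[1]]
  expect_equal(stP$l, st$l, tolerance = 1e-9)
  expect_equal(stP$f, st$f, tolerance = 1e-9)
  expect_equal(stP$stat, st$stat, tolerance = 1e-9)
  # permuted sample i is original sample perm[i]
  expect_equal(stP$logLik, st$logLik[perm, ], tolerance = 1e-9)
})

test_that("iteration stays inside deviation bounds and frequency in [0,1]", {
  set.seed(66)
  hist <- makeNormalHist(seed = 67)
  wh <- transformHistogram(hist, 30L)
  for (i in 1:5) {
    sim <- simulateWindow(runif(1, 500, 8000), runif(1, 0.1, 0.9),
                          nSamples = 10, seed = 300 + i)
    states <- estimateWindow(sim$deltaList, wh, nullSd = 15, minLen = 50)
    for (st in states) {
      expect_gte(st$f, 0); expect_lte(st$f, 1)
      allDelta <- unlist(sim$deltaList)
      expect_gte(st$l, min(allDelta)); expect_lte(st$l, max(allDelta))
    }
  }
})

test_that("start position is one past the rightmost supporting end", {
  expect_identical(estimateStartPosition(c(1199, 1205, 1201)), 1206L)
  expect_identical(estimateStartPosition(c(870)), 871L)
  expect_identical(estimateStartPosition(numeric(), fallback = 990L), 990L)
})

test_that("oracle equivalence of the update equations on small instances", {
  set.seed(88)
  deltas <- c(-30L, 0L, 30L, 770L, 800L, 830L)
  probs <- c(0.1, 0.4, 0.1, 0.05, 0.25, 0.1)
  wh <- makeWindowHist(deltas, probs)
  H <- oracleH(deltas, probs)
  l <- 800
  for (rep in 1:5) {
    f <- runif(1, 0.1, 0.9)
    deltaList <- lapply(1:3, function(s) sample(deltas, sample(1:8, 1), TRUE))
    Llist <- lapply(deltaList, oracleGenotypeLik, H = H, l = l)
    Wlist <- lapply(Llist, oracleWeights, f = f)
    WMat <- do.call(rbind, Wlist)
    expect_equal(updateAlleleFrequency(WMat), oracleUpdateF(Wlist),
                 tolerance = 1e-9)
    # Eq. 12 per pair
    for (s in 1:3) for (d in deltaList[[s]])
      expect_equal(shiftProbability(d, wh, l, WMat[s, 2], WMat[s, 3]),
                   oracleShiftP(d, H, l, 0, WMat[s, 2], WMat[s, 3]),
                   tolerance = 1e-9)
    # Eq. 13 jointly
    P <- unlist(lapply(1:3, function(s)
      shiftProbability(deltaList[[s]], wh, l, WMat[s, 2], WMat[s, 3])))
    expect_equal(updateLength(unlist(deltaList), P),
                 oracleUpdateL(deltaList, list(H, H, H), l, 0, Wlist),
                 tolerance = 1e-9)
  }
})
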