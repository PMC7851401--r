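# Iterative per-window estimation of deletion length, allele frequency,
# weights and start position.

# --- fast lookup table over a common deviation grid -------------------------

# whList: list of WindowHistogram (one per histogram column)
buildLookup <- function(whList) {
  dmin <- min(vapply(whList, function(w) w@deltaMin, 1L))
  dmax <- max(vapply(whList, function(w) w@deltaMin + length(w@probs) - 1L, 1L))
  floorv <- whList[[1L]]@floor
  M <- matrix(floorv, nrow = dmax - dmin + 1L, ncol = length(whList))
  for (k in seq_along(whList)) {
    w <- whList[[k]]
    i0 <- w@deltaMin - dmin + 1L
    M[i0:(i0 + length(w@probs) - 1L), k] <- w@probs
  }
  list(M = M, dmin = dmin, floor = floorv, n = nrow(M))
}

hLookM <- function(x, col, lk) {
  i <- as.integer(round(x)) - lk$dmin + 1L
  out <- rep(lk$floor, length(x))
  ok <- i >= 1L & i <= lk$n
  out[ok] <- lk$M[i[ok] + (col[ok] - 1L) * lk$n]
  out
}

# per-sample sums with absent samples filled as 0; x may be a matrix
rowsumFull <- function(x, sampleIdx, nSamples) {
  x <- as.matrix(x)
  rs <- rowsum(x, sampleIdx, reorder = TRUE)
  out <- matrix(0, nrow = nSamples, ncol = ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# type-7 third quartile without quantile()'s name-formatting overhead;
# exactly quantile(x, 0.75, type = 7)
fastQ3 <- function(x) {
  n <- length(x)
  if (n == 1L) return(as.numeric(x))
  h <- 1 + 0.75 * (n - 1)
  lo <- floor(h)
  hi <- min(lo + 1, n)
  s <- sort.int(x, partial = unique(c(lo, hi)))
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# greedy clustering of per-sample quartiles into initial lengths
clusterQuartiles <- function(q3, nullSd, minLen, clusterMinGap = 40) {
  if (!length(q3)) return(numeric())
  gap <- max(sqrt(mean(nullSd^2)), clusterMinGap)
  q3 <- sort(q3, decreasing = TRUE)
  inits <- numeric()
  seed <- q3[1L]
  members <- q3[1L]
  for (q in q3[-1L]) {
    if (abs(seed - q) <= gap) {
      members <- c(members, q)
    } else {
      inits <- c(inits, median(members))
      seed <- q
      members <- q
    }
  }
  inits <- c(inits, median(members))
  inits[inits >= minLen]
}

# --- exported building blocks ----------------------------------------------

#' Initial deletion lengths for a window
#'
#' Third quartiles of the per-sample insert-size deviations are clustered
#' greedily (descending order; a sample joins the current cluster when its
#' quartile is within max(pooled null sd, \code{clusterMinGap}) of the
#' cluster seed). Each cluster yields one initial length, the median of its
#' quartiles; clusters below the minimum detectable length are dropped.
#'
#' @param deltaList list of numeric vectors: insert-size deviations per
#'   sample (samples without pairs may be empty).
#' @param nullSd numeric vector of per-sample null standard deviations.
#' @param minLen minimum detectable deletion length (bp).
#' @param clusterMinGap lower bound of the clustering gap (bp, default 40).
#' @return numeric vector of initial lengths (possibly empty).
#' @export
initializeLengths <- function(deltaList, nullSd, minLen, clusterMinGap = 40) {
  has <- lengths(deltaList) > 0L
  q3 <- vapply(deltaList[has], fastQ3, numeric(1))
  clusterQuartiles(q3, rep_len(nullSd, length(deltaList)), minLen,
                   clusterMinGap)
}

#' Initial allele frequency for a window
#'
#' Fraction of deletion-supporting read pairs (deviation above
#' \code{supportSdMult} null standard deviations) among all pairs in the
#' window, clamped away from the boundaries to 1/(2 n) and 1 - 1/(2 n) for
#' n samples.
#'
#' @param delta numeric vector of deviations of all pairs in the window
#'   (all samples pooled).
#' @param sigma null standard deviation (bp); may be a vector parallel to
#'   \code{delta} for per-read-group thresholds.
#' @param nSamples number of samples in the cohort.
#' @param supportSdMult support threshold multiplier (default 3).
#' @return allele frequency, or \code{NA} when there are no pairs.
#' @export
initializeAlleleFrequency <- function(delta, sigma, nSamples, supportSdMult = 3) {
  if (!length(delta)) return(NA_real_)
  f <- mean(delta > supportSdMult * sigma)
  lo <- 1 / (2 * nSamples)
  min(max(f, lo), 1 - lo)
}

#' Allele-frequency update from genotype weights
#'
#' The expected deletion allele count per sample is a1 + 2 a2; averaging
#' over samples and dividing by the two alleles gives the updated cohort
#' frequency.
#'
#' @param weights numeric matrix samples x 3 of genotype weights.
#' @return updated allele frequency in [0, 1].
#' @export
updateAlleleFrequency <- function(weights) {
  stopifnot(is.matrix(weights), ncol(weights) == 3L)
  sum(weights[, 2L] + 2 * weights[, 3L]) / (2 * nrow(weights))
}

#' Probability that a deviation reflects the deletion
#'
#' For one read pair, the probability that its insert-size deviation arose
#' from the null distribution shifted by the deletion length l rather than
#' by the reference shift epsilon, given the sample's genotype weights:
#' P = a1 * H(delta - l) / (H(delta - eps) + H(delta - l)) + a2.
#'
#' @param delta numeric vector of deviations.
#' @param wh the sample's \code{\link{WindowHistogram}}.
#' @param l current deletion length (bp).
#' @param a1,a2 the sample's heterozygous / homozygous genotype weights.
#' @param eps reference shift (bp, default 0).
#' @return numeric vector of probabilities in [0, 1].
#' @export
shiftProbability <- function(delta, wh, l, a1, a2, eps = 0) {
  h0 <- hLookup(wh, delta - eps)
  hl <- hLookup(wh, delta - l)
  a1 * hl / (h0 + hl) + a2
}

#' Deletion-length update
#'
#' Weighted average of all insert-size deviations across samples, weighted
#' by their probabilities of reflecting the deletion.
#'
#' @param delta numeric vector of deviations (all samples pooled).
#' @param P numeric vector of shift probabilities
#'   (\code{\link{shiftProbability}}).
#' @return updated length, or \code{NA} when the total weight is zero
#'   (iteration aborted).
#' @export
updateLength <- function(delta, P) {
  sP <- sum(P)
  if (sP <= 0) return(NA_real_)
  sum(delta * P) / sP
}

#' Deletion start position from supporting pairs
#'
#' The deletion is taken to start one base after the rightmost aligned
#' forward-read end among the pairs supporting the deletion estimate.
#'
#' @param fwdEnds 0-based rightmost aligned positions (clip-extended) of
#'   the forward reads of supporting pairs.
#' @param fallback position returned when there are no supporting pairs
#'   (the window start).
#' @return 0-based start position.
#' @examples
#' estimateStartPosition(c(1199, 1205, 1201))  # 1206
#' @export
estimateStartPosition <- function(fwdEnds, fallback = NA_integer_) {
  if (!length(fwdEnds)) return(as.integer(fallback))
  as.integer(max(fwdEnds) + 1L)
}

# --- the window engine ------------------------------------------------------

# Single implementation used by iterateWindow() and the joint caller.
# delta/sampleIdx/histCol/fwdEnd are parallel vectors over all pairs in the
# window; lk is a buildLookup() table; eps has one entry per sample.
windowEngine <- function(delta, sampleIdx, nSamples, histCol, lk, eps,
                         fwdEnd, lInit, fInit, config, minLen,
                         windowStart = 0L) {
  l <- lInit
  f <- fInit
  deps <- delta - eps[sampleIdx]
  seen <- character()
  converged <- FALSE
  status <- "maxiter"
  h0 <- hLookM(deps, histCol, lk)
  for (it in seq_len(config$maxIterations)) {
    hl <- hLookM(delta - l, histCol, lk)
    ll <- rowsumFull(cbind(log(h0), log((h0 + hl) / 2), log(hl)),
                     sampleIdx, nSamples)
    W <- genotypeWeightsMatrix(ll, f)
    fNew <- sum(W[, 2L] + 2 * W[, 3L]) / (2 * nSamples)
    P <- W[sampleIdx, 2L] * hl / (h0 + hl) + W[sampleIdx, 3L]
    # pairs outside the support of both the null and the shifted model are
    # uninformative for this length hypothesis (e.g. they belong to a
    # different deletion length); they must not drag the length update
    P[h0 <= lk$floor & hl <= lk$floor] <- 0
    sP <- sum(P)
    if (sP <= 0)
      return(list(status = "nocall", reason = "zero support"))
    lNew <- sum(delta * P) / sP
    if (!is.finite(lNew) || lNew < minLen)
      return(list(status = "nocall", reason = "length below minimum"))
    if (abs(lNew - l) <= config$lenTolBp && abs(fNew - f) <= config$afTol) {
      l <- lNew; f <- fNew
      converged <- TRUE
      status <- "converged"
      break
    }
    key <- paste(round(lNew), round(fNew, 4L))
    if (key %in% seen) {               # oscillation: keep current state
      l <- lNew; f <- fNew
      status <- "oscillation"
      break
    }
    seen <- c(seen, key)
    l <- lNew
    f <- fNew
  }
  hl <- hLookM(delta - l, histCol, lk)
  ll <- rowsumFull(cbind(log(h0), log((h0 + hl) / 2), log(hl)),
                   sampleIdx, nSamples)
  W <- genotypeWeightsMatrix(ll, f)
  lrt <- likelihoodRatioTest(ll, W, config)
  P <- W[sampleIdx, 2L] * hl / (h0 + hl) + W[sampleIdx, 3L]
  P[h0 <= lk$floor & hl <= lk$floor] <- 0
  # a pair marks the start only if its own deviation favours the deletion
  # model: a homozygous carrier has P ~ 1 for all its pairs, including the
  # non-deviated ones downstream of the deletion end
  supporting <- P >= 0.5 & hl > h0
  start <- estimateStartPosition(fwdEnd[supporting], fallback = windowStart)
  cnt <- rowsumFull(rep(1, length(delta)), sampleIdx, nSamples)[, 1L]
  list(status = status, converged = converged, l = l, f = f,
       logLik = ll, weights = W, stat = lrt$stat, reject = lrt$reject,
       logLambda = lrt$logLambda, start = start, pairCount = cnt,
       iterations = it)
}

#' Iterative window estimation
#'
#' Runs the full estimation loop for one genomic window and one length
#' initialisation: genotype likelihoods, genotype weights,
#' allele-frequency update, shift probabilities and length update, until
#' length and frequency converge (within \code{lenTolBp} / \code{afTol})
#' or a termination condition fires (maximum iterations, length collapsing
#' below the minimum detectable length, oscillating states). The converged
#' state is passed through the likelihood-ratio test.
#'
#' @param deltaList list of numeric vectors: per-sample insert-size
#'   deviations of the pairs overlapping the window.
#' @param whList list of \code{\link{WindowHistogram}}, one per sample (a
#'   single histogram is recycled).
#' @param lInit initial deletion length (bp).
#' @param fInit initial allele frequency.
#' @param config a \code{\link{jdConfig}}.
#' @param eps per-sample reference shifts (recycled scalar allowed).
#' @param fwdEndList list of per-sample 0-based forward-read end positions
#'   parallel to \code{deltaList} (optional; start estimation falls back to
#'   \code{windowStart} without it).
#' @param minLen minimum detectable length; default 0 (no constraint).
#' @param windowStart 0-based window start used as start-position fallback.
#' @return a list describing the converged state: \code{l}, \code{f},
#'   \code{logLik} (samples x 3), \code{weights}, \code{stat}
#'   (-2 log Lambda), \code{reject}, \code{start}, \code{status}
#'   (\code{"converged"}, \code{"maxiter"}, \code{"oscillation"} or
#'   \code{"nocall"}).
#' @export
iterateWindow <- function(deltaList, whList, lInit, fInit,
                          config = jdConfig(), eps = 0,
                          fwdEndList = NULL, minLen = 0,
                          windowStart = 0L) {
  n <- length(deltaList)
  if (is(whList, "WindowHistogram")) whList <- list(whList)
  whIdx <- if (length(whList) == 1L) rep(1L, n) else seq_len(n)
  stopifnot(length(whIdx) == n)
  delta <- unlist(deltaList, use.names = FALSE)
  if (is.null(delta)) delta <- numeric()
  lens <- lengths(deltaList)
  sampleIdx <- rep(seq_len(n), lens)
  histCol <- whIdx[sampleIdx]
  eps <- rep_len(eps, n)
  fwdEnd <- if (is.null(fwdEndList)) rep(NA_real_, length(delta)) else
    unlist(fwdEndList, use.names = FALSE)
  lk <- buildLookup(whList)
  windowEngine(delta, sampleIdx, n, histCol, lk, eps, fwdEnd,
               lInit, fInit, config, minLen, windowStart)
}

#' Full per-window estimation with automatic initialisation
#'
#' Derives length initialisations by quartile clustering
#' (\code{\link{initializeLengths}}), sets the initial allele frequency
#' from the fraction of supporting pairs, and runs
#' \code{\link{iterateWindow}} once per initialisation.
#'
#' @inheritParams iterateWindow
#' @param nullSd per-sample null standard deviations (used for support
#'   threshold and clustering gap).
#' @return list of converged states (possibly empty when no initialisation
#'   reaches the minimum detectable length).
#' @export
estimateWindow <- function(deltaList, whList, nullSd,
                           config = jdConfig(), eps = 0,
                           fwdEndList = NULL, minLen = NULL,
                           windowStart = 0L) {
  n <- length(deltaList)
  if (is.null(minLen)) minLen <- if (is.na(config$minLen)) 0 else config$minLen
  nullSd <- rep_len(nullSd, n)
  inits <- initializeLengths(deltaList, nullSd, minLen, config$clusterMinGap)
  if (!length(inits)) return(list())
  delta <- unlist(deltaList, use.names = FALSE)
  sigma <- rep(nullSd, lengths(deltaList))
  f0 <- initializeAlleleFrequency(delta, sigma, n, config$supportSdMult)
  if (is.na(f0)) return(list())
  states <- lapply(inits, function(l0)
    iterateWindow(deltaList, whList, l0, f0, config, eps,
                  fwdEndList, minLen, windowStart))
  Filter(function(st) st$status != "nocall", states)
}
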