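# Window likelihood model. All genotype likelihoods are handled in natural
# log domain; the window histogram is floored so products never vanish.

#' Transform a null histogram for a window
#'
#' Converts the insert-size histogram of a sample into the relative
#' likelihood H(delta) of observing a read pair with insert-size deviation
#' delta overlapping a window of size w. A pair with insert size i can
#' overlap i + w - 1 placements of the window, so each insert size is
#' weighted by its length before normalisation. Probabilities below the
#' floor are replaced by the floor, which also serves as the out-of-support
#' value.
#'
#' @param hist an \code{\link{InsertSizeHistogram}}.
#' @param w window size in bp.
#' @param floor probability floor (default 1e-10).
#' @return a \code{\link{WindowHistogram}} over integer deviations
#'   delta = i - round(mean).
#' @export
transformHistogram <- function(hist, w = 30L, floor = 1e-10) {
  stopifnot(is(hist, "InsertSizeHistogram"), w >= 1L)
  if (hist@total <= 0) stop("empty histogram")
  sizes <- hist@offset + seq_along(hist@counts) - 1L
  mass <- hist@counts * (sizes + w - 1)
  probs <- mass / sum(mass)
  probs[probs < floor] <- floor
  mu0 <- as.integer(round(hist@mean))
  new("WindowHistogram", probs = probs,
      deltaMin = as.integer(hist@offset - mu0), floor = floor)
}

#' Look up window-histogram probabilities
#'
#' @param wh a \code{\link{WindowHistogram}}.
#' @param delta numeric vector of insert-size deviations (bp); rounded to
#'   the integer grid.
#' @return numeric vector of probabilities; deviations outside the support
#'   give the floor.
#' @export
hLookup <- function(wh, delta) {
  i <- as.integer(round(delta)) - wh@deltaMin + 1L
  out <- rep(wh@floor, length(delta))
  ok <- i >= 1L & i <= length(wh@probs)
  out[ok] <- wh@probs[i[ok]]
  out
}

#' Genotype log-likelihoods of one sample in one window
#'
#' For deviations Delta of the read pairs overlapping the window, the three
#' genotype likelihoods are products over pairs: the noncarrier model
#' evaluates each deviation against the (epsilon-shifted) null, the
#' homozygous model against the null shifted by the deletion length l, and
#' the heterozygous model against the equal mixture of the two.
#'
#' @param delta numeric vector of insert-size deviations (possibly empty).
#' @param wh the sample's \code{\link{WindowHistogram}}.
#' @param l deletion length (bp), > 0.
#' @param eps sample-specific reference shift (bp), default 0.
#' @return named numeric vector \code{c(L0, L1, L2)} of natural-log
#'   likelihoods; an empty deviation list gives \code{c(0, 0, 0)}
#'   (likelihood 1 for every genotype).
#' @export
genotypeLikelihoods <- function(delta, wh, l, eps = 0) {
  stopifnot(l > 0)
  if (length(delta) == 0L)
    return(c(L0 = 0, L1 = 0, L2 = 0))
  h0 <- hLookup(wh, delta - eps)
  hl <- hLookup(wh, delta - l)
  c(L0 = sum(log(h0)),
    L1 = sum(log((h0 + hl) / 2)),
    L2 = sum(log(hl)))
}

#' Expected genotype frequencies at allele frequency f
#'
#' Hardy-Weinberg genotype priors ((1-f)^2, 2f(1-f), f^2) used to couple
#' the per-sample weights to the population allele frequency.
#'
#' @param f allele frequency in [0, 1].
#' @return numeric vector of length 3 summing to 1.
#' @examples
#' genotypeFrequencyPriors(0.2)  # 0.64 0.32 0.04
#' @export
genotypeFrequencyPriors <- function(f) {
  if (!is.finite(f) || f < 0 || f > 1)
    stop("allele frequency must be in [0, 1]")
  c((1 - f)^2, 2 * f * (1 - f), f^2)
}

#' Sample- and genotype-specific weights
#'
#' Combines the data likelihood of each genotype with its expected frequency
#' at allele frequency f into normalised posterior-like weights. Carriers
#' receive high weight for carrier genotypes; noncarriers are down-weighted
#' in the deletion model accordingly.
#'
#' @param logLik numeric vector of length 3: natural-log genotype
#'   likelihoods (see \code{\link{genotypeLikelihoods}}).
#' @param f allele frequency in [0, 1].
#' @return numeric vector \code{c(a0, a1, a2)} summing to 1.
#' @export
genotypeWeights <- function(logLik, f) {
  stopifnot(length(logLik) == 3L, all(is.finite(logLik)))
  pri <- genotypeFrequencyPriors(f)
  num <- exp(logLik - max(logLik)) * pri
  s <- sum(num)
  if (s <= 0) stop("degenerate weights: all numerators zero")
  unname(num / s)
}

# vectorised weights across samples: logLik and result are n x 3 matrices
genotypeWeightsMatrix <- function(logLik, f) {
  pri <- genotypeFrequencyPriors(f)
  mx <- pmax(logLik[, 1L], logLik[, 2L], logLik[, 3L])
  num <- exp(logLik - mx) * rep(pri, each = nrow(logLik))
  num / rowSums(num)
}

#' Joint likelihood-ratio test for a deletion in a window
#'
#' Compares the relative likelihood of the reference model (all samples
#' noncarriers, prior 1 - pi) against the deletion model of length l, in
#' which every sample contributes its genotype likelihoods mixed by the
#' sample-specific weights (prior pi). The null hypothesis "no deletion" is
#' rejected when -2 log Lambda reaches the chi-square(1 df) quantile at
#' 1 - alpha.
#'
#' @param logLik numeric matrix samples x 3 of natural-log genotype
#'   likelihoods.
#' @param weights numeric matrix samples x 3 of genotype weights (rows sum
#'   to 1).
#' @param config a \code{\link{jdConfig}} (uses \code{priorPi} and the
#'   precomputed chi-square cutoff).
#' @return list with \code{logLambda} (natural log of the likelihood
#'   ratio), \code{stat} (-2 log Lambda) and \code{reject} (logical).
#' @export
likelihoodRatioTest <- function(logLik, weights, config = jdConfig()) {
  stopifnot(is.matrix(logLik), ncol(logLik) == 3L,
            identical(dim(logLik), dim(weights)), nrow(logLik) >= 1L)
  pi0 <- config$priorPi
  logNull <- log1p(-pi0) + sum(logLik[, 1L])
  m <- pmax(logLik[, 1L], logLik[, 2L], logLik[, 3L])
  mix <- rowSums(weights * exp(logLik - m))
  mix <- pmax(mix, .Machine$double.xmin)
  logAlt <- log(pi0) + sum(m + log(mix))
  logLambda <- logNull - logAlt
  stat <- -2 * logLambda
  list(logLambda = logLambda, stat = stat,
       reject = stat >= config$chi2Cutoff)
}

#' Minimum detectable deletion length
#'
#' Derived from the spread of the null insert-size distribution: half the
#' 95th percentile of the absolute deviation |i - mean| (about one standard
#' deviation for near-normal inserts). Deletions shorter than this cannot
#' be separated from insert-size noise by the likelihood ratio test.
#'
#' @param histograms list of \code{\link{InsertSizeHistogram}}.
#' @return numeric length in bp (maximum over histograms).
#' @export
minDetectableLength <- function(histograms) {
  q <- vapply(histograms, function(h) {
    sizes <- h@offset + seq_along(h@counts) - 1L
    dev <- abs(sizes - h@mean)
    o <- order(dev)
    cw <- cumsum(h@counts[o]) / h@total
    dev[o][which(cw >= 0.95)[1L]]
  }, numeric(1))
  0.5 * max(q)
}
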