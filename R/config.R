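#' Configuration for profiling, calling and genotyping
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Pass individual overrides as named arguments.
#'
#' @param windowSize genomic window size in bp over which the likelihood
#'   ratio test is performed (default 30).
#' @param priorPi prior probability of observing a deletion in a window
#'   (default 1e-4).
#' @param chi2Alpha one-tailed P value threshold for rejecting the null
#'   hypothesis of the likelihood ratio test, 1 degree of freedom
#'   (default 0.01).
#' @param histFloor probability floor of the window-transformed histogram;
#'   keeps likelihood products away from zero (default 1e-10).
#' @param minMapq minimum mapping quality for a read pair to enter a
#'   profile (default 30).
#' @param recordInsertCap optional cap on the insert size of stored records
#'   (bp); \code{Inf} keeps all pairs so that long deletions remain visible.
#' @param histInsertCapSd the null histogram support is capped at
#'   mean + histInsertCapSd * sd during sampling (default 50).
#' @param maxSamplePairs maximum pairs sampled per read group when
#'   estimating the null insert-size distribution (default 100000).
#' @param minSamplePairs hard minimum of sampled pairs below which null
#'   estimation fails (default 1000).
#' @param maxIterations maximum iterations of the per-window parameter
#'   estimation (default 15).
#' @param lenTolBp convergence tolerance on the deletion length (default 2).
#' @param afTol convergence tolerance on the allele frequency (default 1e-3).
#' @param supportSdMult a read pair supports a deletion when its insert-size
#'   deviation exceeds this multiple of the null sd (default 3).
#' @param minLen minimum detectable deletion length in bp; \code{NA} derives
#'   it as 0.5 x the 95th percentile of |deviation| under the null.
#' @param clusterMinGap greedy length-initialisation clustering merges
#'   samples whose deviation third quartiles differ by at most
#'   max(pooled sd, clusterMinGap) bp (default 40).
#' @param epsilon sample-specific reference shift (bp) applied to the null
#'   model; scalar or per-sample named vector (default 0).
#' @param localRecenter logical; re-estimate epsilon per window as the
#'   capped median of non-supporting deviations (default FALSE).
#' @param mergeStartTol windows merge when their predicted starts differ by
#'   at most this many bp; \code{NA} uses max(length/2, 3 * windowSize).
#' @param mergeLenTolFrac windows merge when their relative length
#'   difference is at most this fraction (default 0.25).
#' @param minPairs a sample is genotyped at a locus only with at least this
#'   many read pairs (default 3).
#' @param coverageMult a sample is not genotyped when its pair count exceeds
#'   this multiple of the cohort median at the locus (default 4).
#' @return a named list with class \code{"jdConfig"}.
#' @examples
#' cfg <- jdConfig(windowSize = 30, priorPi = 1e-4)
#' cfg$chi2Cutoff  # precomputed chi-square rejection boundary
#' @export
jdConfig <- function(windowSize = 30L,
                     priorPi = 1e-4,
                     chi2Alpha = 0.01,
                     histFloor = 1e-10,
                     minMapq = 30L,
                     recordInsertCap = Inf,
                     histInsertCapSd = 50,
                     maxSamplePairs = 100000L,
                     minSamplePairs = 1000L,
                     maxIterations = 15L,
                     lenTolBp = 2,
                     afTol = 1e-3,
                     supportSdMult = 3,
                     minLen = NA_real_,
                     clusterMinGap = 40,
                     epsilon = 0,
                     localRecenter = FALSE,
                     mergeStartTol = NA_real_,
                     mergeLenTolFrac = 0.25,
                     minPairs = 3L,
                     coverageMult = 4) {
  cfg <- list(
    windowSize = as.integer(windowSize),
    priorPi = priorPi,
    chi2Alpha = chi2Alpha,
    histFloor = histFloor,
    minMapq = as.integer(minMapq),
    recordInsertCap = recordInsertCap,
    histInsertCapSd = histInsertCapSd,
    maxSamplePairs = as.integer(maxSamplePairs),
    minSamplePairs = as.integer(minSamplePairs),
    maxIterations = as.integer(maxIterations),
    lenTolBp = lenTolBp,
    afTol = afTol,
    supportSdMult = supportSdMult,
    minLen = minLen,
    clusterMinGap = clusterMinGap,
    epsilon = epsilon,
    localRecenter = isTRUE(localRecenter),
    mergeStartTol = mergeStartTol,
    mergeLenTolFrac = mergeLenTolFrac,
    minPairs = as.integer(minPairs),
    coverageMult = coverageMult
  )
  stopifnot(cfg$windowSize >= 1L, cfg$priorPi > 0, cfg$priorPi < 1,
            cfg$maxIterations >= 1L)
  # rejection boundary for -2 log Lambda, precomputed once
  cfg$chi2Cutoff <- qchisq(1 - chi2Alpha, df = 1)
  class(cfg) <- "jdConfig"
  cfg
}

#' @export
print.jdConfig <- function(x, ...) {
  cat("joindel configuration:\n")
  for (k in setdiff(names(x), "chi2Cutoff"))
    cat(sprintf("  %-16s %s\n", k, paste(format(x[[k]]), collapse = ",")))
  invisible(x)
}
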