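# Combine consecutive significant windows supporting the same deletion
# into nonredundant calls.

#' Sort candidate windows
#'
#' Candidate windows are the (window, deletion length) pairs whose null
#' hypothesis was rejected. They are ordered ascending by predicted start
#' position, then deletion length, then likelihood ratio (a stable
#' lexicographic sort), which is the traversal order of the merge pass.
#'
#' @param cands data.frame with columns \code{contig}, \code{start}
#'   (0-based predicted deletion start), \code{len}, \code{logLambda}
#'   (natural log of the likelihood ratio) and \code{stat}; list columns
#'   \code{logLik} (samples x 3 matrices) and \code{pairCount} are carried
#'   along.
#' @return the sorted data.frame.
#' @export
sortCandidates <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  stopifnot(length(unique(cands$contig)) == 1L)
  o <- order(cands$start, cands$len, cands$logLambda)
  out <- cands[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge candidate windows into deletion calls
#'
#' Single left-to-right pass over the sorted candidates: a window joins the
#' current group when its predicted start is within \code{startTol} of the
#' group seed and the relative length difference is at most
#' \code{lenTolFrac}. The emitted call takes the median start and median
#' length over the group, the mean of the per-sample log genotype
#' likelihoods, the mean pair counts, and the maximum test statistic. The
#' pass then continues from the first uncombined window, so every input
#' window belongs to exactly one call.
#'
#' @param cands sorted candidate data.frame (see
#'   \code{\link{sortCandidates}}).
#' @param config a \code{\link{jdConfig}}; \code{mergeStartTol = NA}
#'   defaults to max(length/2, 3 * windowSize) per group seed.
#' @return data.frame of calls with columns \code{contig}, \code{start},
#'   \code{len}, \code{stat}, \code{nWindows} and list columns
#'   \code{logLik}, \code{pairCount}.
#' @export
mergeCandidates <- function(cands, config = jdConfig()) {
  n <- nrow(cands)
  empty <- data.frame(contig = integer(), start = integer(),
                      len = numeric(), stat = numeric(),
                      nWindows = integer())
  if (n == 0L) {
    empty$logLik <- list()
    empty$pairCount <- list()
    return(empty)
  }
  if (is.unsorted(cands$start)) stop("candidates must be sorted; see sortCandidates()")
  # left-to-right pass over group summaries, repeated to a fixed point so
  # that no two emitted calls still satisfy the merge criteria (summary
  # medians move when windows combine); the first pass acts on the sorted
  # windows themselves
  groups <- as.list(seq_len(n))
  repeat {
    st <- vapply(groups, function(g) median(cands$start[g]), numeric(1))
    ln <- vapply(groups, function(g) median(cands$len[g]), numeric(1))
    o <- order(st, ln)
    groups <- groups[o]; st <- st[o]; ln <- ln[o]
    used <- logical(length(groups))
    newGroups <- vector("list", length(groups))
    nNew <- 0L
    mergedAny <- FALSE
    for (i in seq_along(groups)) {
      if (used[i]) next
      used[i] <- TRUE
      acc <- groups[[i]]
      startTol <- if (is.na(config$mergeStartTol))
        max(ln[i] / 2, 3 * config$windowSize) else config$mergeStartTol
      k <- i + 1L
      while (k <= length(groups)) {
        if (st[k] - st[i] > startTol) break
        if (!used[k]) {
          relLen <- abs(ln[k] - ln[i]) / max(ln[k], ln[i])
          if (relLen <= config$mergeLenTolFrac) {
            used[k] <- TRUE
            acc <- c(acc, groups[[k]])
            mergedAny <- TRUE
          }
        }
        k <- k + 1L
      }
      nNew <- nNew + 1L
      newGroups[[nNew]] <- acc
    }
    groups <- newGroups[seq_len(nNew)]
    if (!mergedAny) break
  }
  out <- lapply(groups, function(grp) {
    list(
      contig = cands$contig[grp[1L]],
      start = as.integer(round(median(cands$start[grp]))),
      len = median(cands$len[grp]),
      stat = max(cands$stat[grp]),
      nWindows = length(grp),
      logLik = Reduce(`+`, cands$logLik[grp]) / length(grp),
      pairCount = Reduce(`+`, cands$pairCount[grp]) / length(grp))
  })
  o <- order(vapply(out, `[[`, 1L, "start"))
  out <- out[o]
  res <- data.frame(
    contig = vapply(out, `[[`, 1L, "contig"),
    start = vapply(out, `[[`, 1L, "start"),
    len = vapply(out, `[[`, 1, "len"),
    stat = vapply(out, `[[`, 1, "stat"),
    nWindows = vapply(out, `[[`, 1L, "nWindows"))
  res$logLik <- lapply(out, `[[`, "logLik")
  res$pairCount <- lapply(out, `[[`, "pairCount")
  res
}
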