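# Joint calling: slide windows over the genome, test every window across
# all samples at once, and merge significant windows into deletion calls.

#' @importFrom IRanges IRanges findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits
NULL

parseRegion <- function(region) {
  if (is.null(region)) return(NULL)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop("malformed region: ", region)
  list(contig = m[2],
       start = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
       end = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_)
}

#' Jointly call deletions across a cohort of profiles
#'
#' Scans the genome in windows of \code{config$windowSize} bp. For every
#' window the insert-size deviations of all samples are collected, deletion
#' length and allele frequency are estimated iteratively, and the weighted
#' likelihood-ratio test decides whether a deletion of the estimated length
#' overlaps the window in any sample. Significant windows are merged into
#' nonredundant calls with genotypes for every sample. Each profile is read
#' exactly once per region, so adding a sample to a cohort only requires
#' its profile.
#'
#' @param profiles list of \code{\link{ReadPairProfile}} objects or paths
#'   to \code{.jdp} files (mixed allowed). All sequence dictionaries must
#'   agree.
#' @param config a \code{\link{jdConfig}}.
#' @param region optional restriction, \code{"contig"} or
#'   \code{"contig:start-end"} (1-based inclusive).
#' @return a \code{\link{DeletionCallSet}}.
#' @export
callDeletions <- function(profiles, config = jdConfig(), region = NULL) {
  if (length(profiles) == 0L) stop("at least one profile is required")
  profiles <- lapply(profiles, function(p)
    if (is.character(p)) readProfile(p) else p)
  sq <- seqDict(profiles[[1L]])
  for (p in profiles[-1L]) {
    if (!identical(seqDict(p), sq)) {
      d <- union(setdiff(names(sq), names(seqDict(p))),
                 setdiff(names(seqDict(p)), names(sq)))
      stop("sequence dictionary mismatch between profiles '",
           sampleId(profiles[[1L]]), "' and '", sampleId(p), "'",
           if (length(d)) paste0(" (contigs: ", paste(d, collapse = ", "), ")"))
    }
  }
  nS <- length(profiles)
  sampleIds <- vapply(profiles, sampleId, "")
  w <- config$windowSize

  # histogram columns: one per (sample, read group)
  whList <- list()
  colMap <- vector("list", nS)
  muByCol <- sdByCol <- numeric()
  sampleSd <- numeric(nS)
  for (s in seq_len(nS)) {
    hs <- histograms(profiles[[s]])
    ids <- integer(0)
    for (h in hs) {
      whList[[length(whList) + 1L]] <-
        transformHistogram(h, w, config$histFloor)
      muByCol <- c(muByCol, h@mean)
      sdByCol <- c(sdByCol, h@sd)
      ids[as.character(h@readGroup)] <- length(whList)
    }
    colMap[[s]] <- ids
    sds <- vapply(hs, function(h) h@sd, numeric(1))
    sampleSd[s] <- sqrt(mean(sds^2))
  }
  lk <- buildLookup(whList)
  minLen <- if (is.na(config$minLen))
    minDetectableLength(unlist(lapply(profiles, histograms))) else config$minLen
  epsS <- rep_len(config$epsilon, nS)

  reg <- parseRegion(region)
  contigs <- seq_along(sq)
  if (!is.null(reg)) {
    ci <- match(reg$contig, names(sq))
    if (is.na(ci)) stop("region contig not in sequence dictionary: ", reg$contig)
    contigs <- ci
  }

  mergedAll <- list()
  for (ci in contigs) {
    # per-sample records on this contig with deviations
    rec <- vector("list", nS)
    for (s in seq_len(nS)) {
      r <- profileRecords(profiles[[s]])
      r <- r[r$contig == ci, , drop = FALSE]
      if (!nrow(r)) { rec[[s]] <- NULL; next }
      hc <- colMap[[s]][as.character(r$readGroup)]
      # start anchor: records carry no aligned read ends, and a forward
      # read crossing the deletion junction is clipped there in real
      # alignments, so fwdStart + readLen overshoots the junction by up to
      # a read length. The rightmost supporting forward-read start bounds
      # the junction from below to within a few bp at normal coverage.
      rec[[s]] <- data.frame(
        fwdStart = r$fwdStart, insert = r$insertSize,
        delta = r$insertSize - muByCol[hc],
        histCol = hc, sample = s,
        fwdEnd = r$fwdStart)
    }
    recs <- do.call(rbind, rec)
    if (is.null(recs) || !nrow(recs)) next
    supporting <- recs$delta > config$supportSdMult * sdByCol[recs$histCol]
    if (!any(supporting)) next
    supRanges <- IRanges(start = recs$fwdStart[supporting] + 1L,
                         width = recs$insert[supporting])
    regions <- reduce(supRanges)
    if (!is.null(reg) && !is.na(reg$start)) {
      keep <- IRanges::start(regions) <= reg$end &
        IRanges::end(regions) >= reg$start
      regions <- regions[keep]
      regions <- IRanges(pmax(IRanges::start(regions), reg$start),
                         pmin(IRanges::end(regions), reg$end))
    }
    if (!length(regions)) next
    pairRanges <- IRanges(start = recs$fwdStart + 1L, width = recs$insert)
    hits <- findOverlaps(pairRanges, regions)
    cand <- list()
    for (ri in seq_along(regions)) {
      idx <- queryHits(hits)[subjectHits(hits) == ri]
      if (!length(idx)) next
      rr <- recs[idx, , drop = FALSE]
      w0 <- (IRanges::start(regions)[ri] - 1L) %/% w
      w1 <- (IRanges::end(regions)[ri] - 1L) %/% w
      fragEnd <- rr$fwdStart + rr$insert
      for (wi in w0:w1) {
        ws <- wi * w
        we <- ws + w
        m <- rr$fwdStart < we & fragEnd > ws
        if (!any(m)) next
        d <- rr$delta[m]; si <- rr$sample[m]; hc <- rr$histCol[m]
        fe <- rr$fwdEnd[m]
        # per-sample third quartiles over contiguous slices of the
        # sample-ordered deviations (avoids split() overhead per window)
        o <- order(si, method = "radix")
        sis <- si[o]; ds <- d[o]
        bnd <- c(0L, which(sis[-1L] != sis[-length(sis)]), length(sis))
        nGrp <- length(bnd) - 1L
        q3 <- numeric(nGrp)
        present <- integer(nGrp)
        for (gi in seq_len(nGrp)) {
          q3[gi] <- fastQ3(ds[(bnd[gi] + 1L):bnd[gi + 1L]])
          present[gi] <- sis[bnd[gi] + 1L]
        }
        inits <- clusterQuartiles(q3, sampleSd[present], minLen,
                                  config$clusterMinGap)
        if (!length(inits)) next
        f0 <- initializeAlleleFrequency(d, sdByCol[hc], nS,
                                        config$supportSdMult)
        eW <- epsS
        if (config$localRecenter) {
          for (s in present) {
            dsub <- d[si == s]
            dsub <- dsub[abs(dsub) <= config$supportSdMult * sampleSd[s]]
            if (length(dsub))
              eW[s] <- max(min(median(dsub), sampleSd[s]), -sampleSd[s])
          }
        }
        for (l0 in inits) {
          st <- windowEngine(d, si, nS, hc, lk, eW, fe, l0, f0,
                             config, minLen, windowStart = ws)
          if (st$status == "nocall" || !st$reject) next
          # self-consistency: the test asks whether a deletion of length l
          # overlaps this window. Flanking windows are reached by the
          # apparent spans of deletion-spanning fragments but estimate an
          # interval that does not contain them; keeping only windows
          # inside their own estimated interval also keeps the per-sample
          # likelihoods of a merged call free of flank mixtures.
          if (st$start > ws || st$start + st$l < we) next
          cand[[length(cand) + 1L]] <- list(
            contig = ci, start = st$start, len = st$l,
            logLambda = st$logLambda, stat = st$stat,
            logLik = st$logLik, pairCount = st$pairCount)
        }
      }
    }
    if (!length(cand)) next
    cdf <- data.frame(
      contig = vapply(cand, `[[`, 1L, "contig"),
      start = vapply(cand, `[[`, 1L, "start"),
      len = vapply(cand, `[[`, 1, "len"),
      logLambda = vapply(cand, `[[`, 1, "logLambda"),
      stat = vapply(cand, `[[`, 1, "stat"))
    cdf$logLik <- lapply(cand, `[[`, "logLik")
    cdf$pairCount <- lapply(cand, `[[`, "pairCount")
    mergedAll[[length(mergedAll) + 1L]] <-
      mergeCandidates(sortCandidates(cdf), config)
  }
  if (!length(mergedAll)) {
    merged <- data.frame(contig = integer(), start = integer(),
                         len = numeric(), stat = numeric(),
                         nWindows = integer())
    merged$logLik <- list()
    merged$pairCount <- list()
  } else {
    merged <- do.call(rbind, mergedAll)
    merged <- merged[order(merged$contig, merged$start), , drop = FALSE]
  }
  makeCallSet(merged, sq, sampleIds, config)
}
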