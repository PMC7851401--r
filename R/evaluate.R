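# Scoring and population/trio QC: call-set matching, filtering, HWE,
# Mendelian error, transmission rate, de novo screening, matrix export.

#' @importFrom GenomicRanges GRanges findOverlaps pintersect
NULL

#' Reciprocal overlap of two intervals
#'
#' min(|intersection|/|a|, |intersection|/|b|); 0 for intervals on
#' different contigs.
#'
#' @param aStart,aEnd,bStart,bEnd half-open interval bounds (vectorised).
#' @param aContig,bContig optional contig labels.
#' @return numeric fraction in [0, 1].
#' @examples
#' reciprocalOverlap(100, 200, 150, 250)  # 0.5
#' @export
reciprocalOverlap <- function(aStart, aEnd, bStart, bEnd,
                              aContig = NULL, bContig = NULL) {
  inter <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
  ro <- pmin(inter / (aEnd - aStart), inter / (bEnd - bStart))
  if (!is.null(aContig) && !is.null(bContig))
    ro[aContig != bContig] <- 0
  ro
}

#' Match a call set against a truth set
#'
#' A call matches a truth variant when their reciprocal overlap reaches the
#' threshold; each truth variant may be matched by only one call. The
#' assignment is greedy in descending overlap, resolving competing matches
#' deterministically.
#'
#' @param calls,truth \code{GRanges} (or \code{DeletionCallSet}, from which
#'   the ranges are taken).
#' @param threshold minimum reciprocal overlap (default 0.5).
#' @return list with \code{recall}, \code{precision}, \code{f1},
#'   \code{nTP}, and a data.frame \code{matches} (call index, truth index,
#'   overlap).
#' @export
matchCallsets <- function(calls, truth, threshold = 0.5) {
  if (is(calls, "DeletionCallSet")) calls <- calls@rowRanges
  if (is(truth, "DeletionCallSet")) truth <- truth@rowRanges
  nC <- length(calls)
  nT <- length(truth)
  matches <- data.frame(call = integer(), truth = integer(),
                        overlap = numeric())
  if (nC && nT) {
    h <- findOverlaps(calls, truth)
    if (length(h)) {
      qi <- queryHits(h); si <- subjectHits(h)
      ro <- reciprocalOverlap(start(calls)[qi] - 1L, end(calls)[qi],
                              start(truth)[si] - 1L, end(truth)[si])
      keep <- ro >= threshold
      qi <- qi[keep]; si <- si[keep]; ro <- ro[keep]
      o <- order(-ro, qi, si)           # deterministic greedy
      usedC <- logical(nC); usedT <- logical(nT)
      sel <- logical(length(o))
      for (k in o) {
        if (!usedC[qi[k]] && !usedT[si[k]]) {
          usedC[qi[k]] <- TRUE; usedT[si[k]] <- TRUE
          sel[k] <- TRUE
        }
      }
      matches <- data.frame(call = qi[sel], truth = si[sel],
                            overlap = ro[sel])
    }
  }
  nTP <- nrow(matches)
  recall <- if (nT) nTP / nT else NA_real_
  precision <- if (nC) nTP / nC else NA_real_
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  list(recall = recall, precision = precision, f1 = f1, nTP = nTP,
       nCalls = nC, nTruth = nT, matches = matches)
}

#' Read a BED file as GRanges
#'
#' @param path BED path (0-based half-open; first three columns used).
#' @return \code{GRanges}.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(GRanges())
  parts <- strsplit(lines, "\t")
  nfield <- lengths(parts)
  if (any(nfield < 3L))
    stop("malformed BED: fewer than 3 fields at line ",
         which(nfield < 3L)[1L])
  chrom <- vapply(parts, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | e < s
  if (any(bad))
    stop("malformed BED: bad coordinates at line ", which(bad)[1L])
  GRanges(chrom, IRanges(start = s + 1L, end = e))
}

#' Filter deletion calls by size, regions and genotype quality
#'
#' Keeps calls within the size range, removes calls with any overlap with
#' the exclusion regions (e.g. centromeres), restricts to calls fully
#' contained in the high-confidence regions when given, and masks
#' genotypes below the GQ threshold as missing.
#'
#' @param callSet a \code{\link{DeletionCallSet}}.
#' @param sizeMin,sizeMax deletion length bounds in bp (defaults 500 and
#'   10000).
#' @param excludeBed optional \code{GRanges} (or BED path): any overlap
#'   removes the call.
#' @param includeBed optional \code{GRanges} (or BED path): calls must be
#'   fully contained.
#' @param gqMin genotypes with GQ below this are set to "./." (default 0).
#' @return the filtered \code{DeletionCallSet}.
#' @export
filterCalls <- function(callSet, sizeMin = 500, sizeMax = 10000,
                        excludeBed = NULL, includeBed = NULL, gqMin = 0) {
  stopifnot(is(callSet, "DeletionCallSet"))
  gr <- callSet@rowRanges
  len <- abs(mcols(gr)$svlen)
  keep <- len >= sizeMin & len <= sizeMax
  if (!is.null(excludeBed)) {
    if (is.character(excludeBed)) excludeBed <- readBed(excludeBed)
    keep <- keep & !IRanges::overlapsAny(gr, excludeBed, ignore.strand = TRUE)
  }
  if (!is.null(includeBed)) {
    if (is.character(includeBed)) includeBed <- readBed(includeBed)
    within <- IRanges::overlapsAny(gr, includeBed, type = "within",
                                   ignore.strand = TRUE)
    keep <- keep & within
  }
  idx <- which(keep)
  GT <- callSet@GT[idx, , drop = FALSE]
  GQ <- callSet@GQ[idx, , drop = FALSE]
  if (gqMin > 0) {
    GT[GQ < gqMin] <- "./."
    # a call with no genotyped sample left carries no information
    nonEmpty <- rowSums(GT != "./.") > 0L
    idx <- idx[nonEmpty]
    GT <- GT[nonEmpty, , drop = FALSE]
    GQ <- GQ[nonEmpty, , drop = FALSE]
  }
  new("DeletionCallSet", rowRanges = gr[idx],
      sampleIds = callSet@sampleIds, GT = GT,
      PL = callSet@PL[idx, , , drop = FALSE], GQ = GQ,
      pairCount = callSet@pairCount[idx, , drop = FALSE])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the P value is
#' the total probability of heterozygote counts no more probable than the
#' observed one. Monomorphic sites have P 1.
#'
#' @param n00,n01,n11 genotype counts (reference hom, het, alternate hom).
#' @return P value.
#' @export
hweExactTest <- function(n00, n01, n11) {
  n <- n00 + n01 + n11
  nA <- 2L * n11 + n01                  # minor allele count (either allele)
  nB <- 2L * n00 + n01
  if (nA > nB) { tmp <- nA; nA <- nB; nB <- tmp }
  if (nA == 0L) return(1)
  hets <- seq(nA %% 2L, nA, by = 2L)    # feasible heterozygote counts
  # log conditional probability of each het count given allele counts
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n01, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg filter over sites
#'
#' @param counts integer matrix sites x 3 of genotype counts (0/0, 0/1,
#'   1/1), or a \code{\link{DeletionCallSet}} whose genotypes are counted.
#' @param alpha P value threshold (default 0.01).
#' @return logical vector: \code{TRUE} for sites to keep.
#' @export
hweFilter <- function(counts, alpha = 0.01) {
  if (is(counts, "DeletionCallSet")) {
    gt <- counts@GT
    counts <- cbind(rowSums(gt == "0/0"), rowSums(gt == "0/1"),
                    rowSums(gt == "1/1"))
  }
  p <- vapply(seq_len(nrow(counts)), function(i)
    hweExactTest(counts[i, 1L], counts[i, 2L], counts[i, 3L]), numeric(1))
  p >= alpha
}

#' Build a trio genotype table from a call set and pedigree
#'
#' @param callSet a \code{\link{DeletionCallSet}}.
#' @param pedigree data.frame with columns \code{child}, \code{father},
#'   \code{mother} (sample ids present in the call set).
#' @param gqMin genotypes below this GQ become missing (default 0).
#' @return data.frame with columns \code{site}, \code{trio},
#'   \code{father}, \code{mother}, \code{child} (integer allele counts,
#'   NA for missing) and the three GQ columns.
#' @export
buildTrioTable <- function(callSet, pedigree, gqMin = 0) {
  g2i <- function(g) c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[g]
  idx <- function(ids) {
    i <- match(ids, callSet@sampleIds)
    if (anyNA(i)) stop("pedigree samples missing from call set: ",
                       paste(ids[is.na(i)], collapse = ", "))
    i
  }
  ci <- idx(pedigree$child); fi <- idx(pedigree$father)
  mi <- idx(pedigree$mother)
  n <- length(callSet@rowRanges)
  res <- do.call(rbind, lapply(seq_along(ci), function(t) {
    gt <- callSet@GT
    gq <- callSet@GQ
    mask <- function(i) {
      g <- unname(g2i(gt[, i]))
      g[gq[, i] < gqMin] <- NA_integer_
      g
    }
    data.frame(site = seq_len(n), trio = t,
               father = mask(fi[t]), mother = mask(mi[t]),
               child = mask(ci[t]),
               fatherGQ = gq[, fi[t]], motherGQ = gq[, mi[t]],
               childGQ = gq[, ci[t]])
  }))
  rownames(res) <- NULL
  res
}

#' Mendelian consistency of a trio genotype combination
#'
#' A child genotype is consistent when one allele can come from each
#' parent (a homozygote contributes that allele, a heterozygote either).
#' Symmetric in the parents. Vectorised; NA in any member gives NA.
#'
#' @param father,mother,child integer allele counts (0, 1, 2).
#' @return logical vector.
#' @export
mendelianConsistent <- function(father, mother, child) {
  lo <- (father == 2L) + (mother == 2L)          # alleles forced to 1
  hi <- 2L - ((father == 0L) + (mother == 0L))   # max transmittable
  child >= lo & child <= hi
}

# rows to ignore: any missing genotype or an all-reference trio
trioIgnored <- function(tab) {
  miss <- is.na(tab$father) | is.na(tab$mother) | is.na(tab$child)
  allRef <- !miss & tab$father == 0L & tab$mother == 0L & tab$child == 0L
  miss | allRef
}

#' Mendelian inheritance error rate over trios
#'
#' Trios with a missing genotype or with all three members 0/0 are
#' ignored. The rate is errors / (errors + consistent).
#'
#' @param trioTable table from \code{\link{buildTrioTable}} (or
#'   \code{\link{simulateTrios}}).
#' @return list with \code{errorRate}, \code{nErrors},
#'   \code{nConsistent}, and \code{consistentPerTrio}.
#' @export
mendelianErrorRate <- function(trioTable) {
  keep <- !trioIgnored(trioTable)
  tt <- trioTable[keep, , drop = FALSE]
  cons <- mendelianConsistent(tt$father, tt$mother, tt$child)
  nErr <- sum(!cons)
  nCon <- sum(cons)
  list(errorRate = if (nErr + nCon > 0) nErr / (nErr + nCon) else NA_real_,
       nErrors = nErr, nConsistent = nCon,
       consistentPerTrio = tapply(cons, tt$trio, sum))
}

#' Transmission rate of the deletion allele
#'
#' In mode \code{"all"}, every heterozygous parent at a non-ignored,
#' Mendelian-consistent site is a transmission opportunity; the number of
#' transmitted deletion alleles is the child's allele count minus the
#' alleles forced by homozygous-carrier parents. In mode
#' \code{"unique_single_parent"}, only sites whose deletion allele is
#' called in exactly one trio are considered, with parental genotypes
#' {0/1, 0/0}; the allele is transmitted iff the child is 0/1. The
#' expected rate under Mendelian inheritance is 50 percent.
#'
#' @param trioTable table from \code{\link{buildTrioTable}}.
#' @param mode \code{"all"} or \code{"unique_single_parent"}.
#' @return list with \code{rate} (percent; NA when nothing is
#'   considered), \code{transmitted}, \code{considered}.
#' @export
transmissionRate <- function(trioTable, mode = c("all", "unique_single_parent")) {
  mode <- match.arg(mode)
  keep <- !trioIgnored(trioTable)
  tt <- trioTable[keep, , drop = FALSE]
  if (mode == "all") {
    cons <- mendelianConsistent(tt$father, tt$mother, tt$child)
    tt <- tt[cons, , drop = FALSE]
    nHet <- (tt$father == 1L) + (tt$mother == 1L)
    forced <- (tt$father == 2L) + (tt$mother == 2L)
    opp <- tt[nHet > 0L, , drop = FALSE]
    transmitted <- sum(opp$child - ((opp$father == 2L) + (opp$mother == 2L)))
    considered <- sum(nHet)
  } else {
    carried <- tt$father > 0L | tt$mother > 0L | tt$child > 0L
    nTriosPerSite <- tapply(carried, tt$site, sum)
    uniq <- as.integer(names(nTriosPerSite))[nTriosPerSite == 1L]
    tt <- tt[tt$site %in% uniq & carried, , drop = FALSE]
    inf <- (tt$father == 1L & tt$mother == 0L) |
      (tt$father == 0L & tt$mother == 1L)
    tt <- tt[inf, , drop = FALSE]
    transmitted <- sum(tt$child == 1L)
    considered <- nrow(tt)
  }
  list(rate = if (considered > 0) 100 * transmitted / considered else NA_real_,
       transmitted = transmitted, considered = considered)
}

#' De novo deletion candidates
#'
#' Sites where the child carries the deletion, both parents are 0/0, and
#' all three genotype qualities reach the threshold.
#'
#' @param trioTable table from \code{\link{buildTrioTable}}.
#' @param gqMin genotype quality threshold (default 50).
#' @return data.frame of candidate rows.
#' @export
deNovoCandidates <- function(trioTable, gqMin = 50) {
  keep <- !trioIgnored(trioTable) &
    trioTable$child >= 1L & trioTable$father == 0L & trioTable$mother == 0L &
    trioTable$fatherGQ >= gqMin & trioTable$motherGQ >= gqMin &
    trioTable$childGQ >= gqMin
  out <- trioTable[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected number of de novo deletions
#'
#' Scales a verified per-trio de novo deletion rate to a cohort size.
#'
#' @param verifiedEvents verified de novo events in the reference study.
#' @param referenceTrios trios in the reference study.
#' @param nTrios trios in the cohort at hand.
#' @return expected count, rounded to 2 decimals.
#' @examples
#' expectedDeNovo(7, 258, 49)  # 1.33
#' @export
expectedDeNovo <- function(verifiedEvents, referenceTrios, nTrios) {
  stopifnot(referenceTrios > 0, nTrios >= 0, verifiedEvents >= 0)
  round(verifiedEvents / referenceTrios * nTrios, 2L)
}

#' Genotype matrix export
#'
#' Converts a genotyped call set into a samples x sites matrix of deletion
#' allele counts (NA for missing genotypes), dropping uninformative
#' (monomorphic) sites. Downstream LD pruning and PCA are left to external
#' tools.
#'
#' @param callSet a \code{\link{DeletionCallSet}}.
#' @return integer matrix samples x polymorphic sites.
#' @export
genotypeMatrix <- function(callSet) {
  g2i <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  m <- matrix(g2i[callSet@GT], nrow = nrow(callSet@GT))  # sites x samples
  m <- t(m)                                              # samples x sites
  rownames(m) <- callSet@sampleIds
  colnames(m) <- sprintf("DEL%05d", seq_len(ncol(m)))
  keep <- apply(m, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
  m[, keep, drop = FALSE]
}
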