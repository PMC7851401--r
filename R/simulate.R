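# Cohort simulator: deletion sets, haplotypes, diploid genotypes,
# fragment-level read-pair streams, trios, and truth files.

#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Simulate a deletion set
#'
#' Draws \code{n} deletions with lengths uniform in \code{lenRange},
#' allele frequencies uniform on (0, 1) and positions uniform on the
#' contig subject to a minimum pairwise gap (placement via uniform spacing
#' of the free sequence, which is exact uniform sampling of valid
#' configurations). Optional exclusion regions (e.g. N-runs) are avoided
#' by bounded rejection sampling.
#'
#' @param n number of deletions.
#' @param contigLength contig length in bp.
#' @param lenRange length range in bp (default c(100, 10000)).
#' @param minGap minimum distance between consecutive deletions
#'   (default 1000).
#' @param contig contig name (default "chrS").
#' @param excludeRegions optional \code{GRanges} or data.frame
#'   (\code{start}, \code{end}, 0-based half-open) that deletions must not
#'   touch.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return \code{GRanges} (1-based) with metadata column \code{af}.
#' @export
simulateDeletionSet <- function(n, contigLength, lenRange = c(100, 10000),
                                minGap = 1000, contig = "chrS",
                                excludeRegions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- setNames(as.integer(contigLength), contig)
  if (n == 0L)
    return(GRanges(seqlengths = sl))
  lens <- as.integer(round(runif(n, lenRange[1], lenRange[2])))
  free <- contigLength - sum(lens) - (n - 1) * minGap
  if (free < 0)
    stop("contig too short to place ", n,
         " deletions with the requested gap; reduce n")
  if (is.null(excludeRegions)) {
    # uniform spacing of the free sequence: exact uniform sampling of the
    # valid (ordered) configurations
    slack <- sort(runif(n, 0, free))
    starts <- as.integer(floor(slack)) + c(0L, cumsum(lens[-n])) +
      (seq_len(n) - 1L) * as.integer(minGap)
  } else {
    ex <- if (is(excludeRegions, "GRanges"))
      IRanges(start(excludeRegions), end(excludeRegions))
    else IRanges(excludeRegions$start + 1L, excludeRegions$end)
    placed <- IRanges()
    starts <- integer(n)
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(200L)) {
        s <- as.integer(floor(runif(1, 0, contigLength - lens[i])))
        cand <- IRanges(s + 1L, width = lens[i])
        # enforce the pairwise gap against already-placed deletions and
        # zero overlap with the exclusion regions
        gapOk <- !IRanges::overlapsAny(cand + as.integer(minGap), placed)
        if (gapOk && !IRanges::overlapsAny(cand, ex)) {
          placed <- c(placed, cand)
          starts[i] <- s
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place deletions outside the exclusion regions; reduce n")
    }
    o <- order(starts)
    starts <- starts[o]
    lens <- lens[o]
  }
  gr <- GRanges(contig, IRanges(start = starts + 1L, width = lens),
                seqlengths = sl)
  mcols(gr)$af <- runif(n)
  gr
}

#' Sample haplotypes and assemble diploid genotypes
#'
#' Each of the 2 n haplotypes carries deletion j independently with
#' probability equal to its allele frequency; consecutive haplotype pairs
#' form diploid individuals whose genotypes are the haplotype sums.
#'
#' @param deletions \code{GRanges} from \code{\link{simulateDeletionSet}}
#'   (metadata column \code{af}).
#' @param nSamples number of diploid individuals.
#' @param seed integer seed.
#' @return a \code{\link{SimCohort}}.
#' @export
simulateGenotypes <- function(deletions, nSamples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nSamples >= 1L)
  m <- length(deletions)
  af <- mcols(deletions)$af
  hap <- matrix(runif(2L * nSamples * m) < rep(af, each = 2L * nSamples),
                nrow = 2L * nSamples)
  g <- hap[seq(1L, 2L * nSamples, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * nSamples, by = 2L), , drop = FALSE]
  storage.mode(g) <- "integer"
  new("SimCohort", deletions = deletions, genotypes = g,
      haplotypes = hap, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# haplotype -> reference coordinate shift bookkeeping for one haplotype
hapJunctions <- function(deletions, carried) {
  if (!any(carried))
    return(list(jun = numeric(0), cum = numeric(0)))
  refStart <- start(deletions)[carried] - 1L   # 0-based
  lens <- width(deletions)[carried]
  o <- order(refStart)
  refStart <- refStart[o]; lens <- lens[o]
  cumBefore <- c(0, cumsum(lens))[seq_along(lens)]
  list(jun = refStart - cumBefore, cum = cumsum(lens))
}

#' Simulate read-pair records for a cohort
#'
#' Fragment-level paired-end simulation: per haplotype, fragments are
#' placed uniformly with insert sizes drawn from a (rounded) normal
#' distribution truncated at twice the read length. Mapping haplotype to
#' reference coordinates makes a fragment spanning a carried deletion of
#' length L appear with insert inflated by L (the deviation signal), while
#' fragments falling inside a homozygously deleted region are simply never
#' generated (the depth signal). Deterministic given the seed.
#'
#' @param cohort a \code{\link{SimCohort}}.
#' @param coverage haploid-summed sequence coverage (default 30).
#' @param readLen read length in bp (default 150).
#' @param insertMean,insertSd insert-size distribution (default 450, 15).
#' @param seed integer seed.
#' @return list of per-sample record data.frames (columns \code{contig},
#'   \code{fwdStart}, \code{insertSize}, \code{readGroup}), sorted by
#'   position.
#' @export
simulateReadPairs <- function(cohort, coverage = 30, readLen = 150L,
                              insertMean = 450, insertSd = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage > 0)
  if (insertMean <= 2 * readLen)
    stop("insertMean must exceed twice the read length")
  dels <- cohort@deletions
  contigLen <- GenomeInfoDb::seqlengths(dels)[1L]
  if (length(dels) == 0L) contigLen <- contigLen  # empty set still simulates
  nS <- nrow(cohort@genotypes)
  out <- vector("list", nS)
  for (s in seq_len(nS)) {
    recs <- vector("list", 2L)
    for (h in 1:2) {
      carried <- cohort@haplotypes[2L * (s - 1L) + h, ]
      jj <- hapJunctions(dels, carried)
      hapLen <- contigLen - sum(width(dels)[carried])
      nFrag <- rpois(1L, hapLen * coverage / 2 / (2 * readLen))
      ins <- pmax(as.integer(round(rnorm(nFrag, insertMean, insertSd))),
                  as.integer(2L * readLen))
      st <- floor(runif(nFrag, 0, pmax(hapLen - ins, 1)))
      shiftAt <- function(x) {
        if (!length(jj$jun)) return(numeric(length(x)))
        k <- findInterval(x, jj$jun)
        c(0, jj$cum)[k + 1L]
      }
      s0 <- shiftAt(st)
      apparent <- as.integer(ins + shiftAt(st + ins - 1) - s0)
      recs[[h]] <- data.frame(
        contig = 1L,
        fwdStart = as.integer(st + s0),
        insertSize = apparent,
        readGroup = 1L)
    }
    r <- rbind(recs[[1L]], recs[[2L]])
    r <- r[order(r$fwdStart), , drop = FALSE]
    rownames(r) <- NULL
    out[[s]] <- r
  }
  names(out) <- sprintf("sample%03d", seq_len(nS))
  out
}

#' Build read-pair profiles for a simulated cohort
#'
#' Convenience wrapper: simulates the read pairs and assembles one
#' \code{\link{ReadPairProfile}} per sample (null distributions estimated
#' from the default sampling regions).
#'
#' @inheritParams simulateReadPairs
#' @param config a \code{\link{jdConfig}}.
#' @return list of \code{ReadPairProfile}.
#' @export
simulateCohortProfiles <- function(cohort, coverage = 30, readLen = 150L,
                                   insertMean = 450, insertSd = 15,
                                   seed = NULL, config = jdConfig()) {
  recs <- simulateReadPairs(cohort, coverage, readLen, insertMean,
                            insertSd, seed)
  sl <- GenomeInfoDb::seqlengths(cohort@deletions)
  lapply(names(recs), function(nm)
    buildProfile(recs[[nm]], sl, nm, config = config, readLen = readLen))
}

#' Simulate the read pairs of a single genomic window
#'
#' Generates the per-sample insert-size deviations observed in one window
#' overlapping a deletion of length \code{l} at allele frequency \code{f}:
#' genotypes are binomial in \code{f}, each haplotype contributes a
#' Poisson number of overlapping pairs, and deviations are normal with
#' mean 0 (reference haplotype) or \code{l} (deletion haplotype).
#'
#' @param l deletion length (bp).
#' @param f allele frequency.
#' @param nSamples cohort size.
#' @param coverage,readLen,insertMean,insertSd sequencing parameters.
#' @param windowSize window size (bp).
#' @param seed integer seed.
#' @return list with \code{deltaList} (per-sample deviations) and
#'   \code{genotypes}.
#' @export
simulateWindow <- function(l, f, nSamples, coverage = 30, readLen = 150L,
                           insertMean = 450, insertSd = 15,
                           windowSize = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(nSamples, 2L, f)
  lam <- coverage * (insertMean + windowSize - 1) / (4 * readLen)
  deltaList <- lapply(seq_len(nSamples), function(s) {
    nRef <- rpois(1L, lam * (2L - g[s]) / 2)
    nDel <- rpois(1L, lam * g[s] / 2)
    round(c(rnorm(nRef, 0, insertSd), rnorm(nDel, l, insertSd)))
  })
  list(deltaList = deltaList, genotypes = g)
}

#' Simulate trio genotypes under Mendelian transmission
#'
#' Parents draw genotypes from the population allele frequencies
#' (Hardy-Weinberg); each child allele is transmitted from the
#' corresponding parent, a heterozygous parent transmitting the deletion
#' allele with probability one half.
#'
#' @param deletions \code{GRanges} with metadata column \code{af}.
#' @param nTrios number of trios.
#' @param seed integer seed.
#' @return a trio genotype table: data.frame with columns \code{site},
#'   \code{trio}, \code{father}, \code{mother}, \code{child} (0/1/2) and
#'   \code{fatherGQ}, \code{motherGQ}, \code{childGQ} (set to 99).
#' @export
simulateTrios <- function(deletions, nTrios, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(deletions)
  af <- mcols(deletions)$af
  drawG <- function() matrix(rbinom(nTrios * m, 2L, rep(af, each = nTrios)),
                             nrow = nTrios)
  fa <- drawG()
  mo <- drawG()
  transmit <- function(g) {
    # allele passed on: hom -> fixed, het -> fair coin
    (g == 2L) + (g == 1L) * (runif(length(g)) < 0.5)
  }
  ch <- transmit(fa) + transmit(mo)
  data.frame(
    site = rep(seq_len(m), each = nTrios),
    trio = rep(seq_len(nTrios), m),
    father = as.integer(fa), mother = as.integer(mo),
    child = as.integer(ch),
    fatherGQ = 99L, motherGQ = 99L, childGQ = 99L)
}

# SimCohort -> DeletionCallSet holding the true genotypes
cohortToCallSet <- function(cohort) {
  g <- cohort@genotypes
  nS <- nrow(g)
  n <- ncol(g)
  sampleIds <- sprintf("sample%03d", seq_len(nS))
  GT <- matrix(c("0/0", "0/1", "1/1")[t(g) + 1L], n, nS)
  af <- colMeans(g) / 2
  gr <- cohort@deletions
  mcols(gr) <- DataFrame(svlen = -width(gr), af = af,
                         stat = rep(NA_real_, n), nWindows = rep(NA_integer_, n))
  colnames(GT) <- sampleIds
  new("DeletionCallSet", rowRanges = gr, sampleIds = sampleIds,
      GT = GT, PL = array(0L, c(n, nS, 3L)),
      GQ = matrix(99L, n, nS, dimnames = list(NULL, sampleIds)),
      pairCount = matrix(NA_real_, n, nS, dimnames = list(NULL, sampleIds)))
}

#' Write simulation truth files
#'
#' Emits the true deletions and genotypes of a simulated cohort as a
#' multi-sample VCF and a BED file (0-based half-open intervals with the
#' population allele frequency in the score column).
#'
#' @param cohort a \code{\link{SimCohort}}.
#' @param vcfPath,bedPath output paths (either may be NULL to skip).
#' @return invisibly, the truth \code{\link{DeletionCallSet}}.
#' @export
writeTruth <- function(cohort, vcfPath = NULL, bedPath = NULL) {
  cs <- cohortToCallSet(cohort)
  if (!is.null(vcfPath)) writeDeletionVcf(cs, vcfPath)
  if (!is.null(bedPath)) {
    gr <- cohort@deletions
    writeLines(sprintf("%s\t%d\t%d\tDEL%05d\t%.6f",
                       as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                       seq_along(gr), mcols(gr)$af),
               bedPath)
  }
  invisible(cs)
}

#' Render read-pair records as a SAM file
#'
#' Writes each simulated pair as two ungapped primary alignments (forward
#' flag 99 / reverse flag 147, MAPQ 60, CIGAR \code{<readLen>M}), sorted by
#' coordinate, for exercising the BAM ingestion path.
#'
#' @param records record data.frame (see \code{\link{simulateReadPairs}}).
#' @param seqlengths named integer vector (sequence dictionary).
#' @param path output SAM path.
#' @param readLen read length used for the reverse-mate position.
#' @param sampleId read-group sample field.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(records, seqlengths, path, readLen = 150L,
                     sampleId = "sim") {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths),
           sprintf("@RG\tID:1\tSM:%s", sampleId))
  n <- nrow(records)
  if (n == 0L) { writeLines(hdr, path); return(invisible(path)) }
  cn <- names(seqlengths)[records$contig]
  qn <- sprintf("p%08d", seq_len(n))
  fwdPos <- records$fwdStart + 1L
  revPos <- records$fwdStart + records$insertSize - readLen + 1L
  cig <- sprintf("%dM", readLen)
  seqs <- strrep("N", readLen)
  fwd <- paste(qn, 99L, cn, fwdPos, 60L, cig, "=", revPos,
               records$insertSize, seqs, "*", "RG:Z:1", sep = "\t")
  rev <- paste(qn, 147L, cn, revPos, 60L, cig, "=", fwdPos,
               -records$insertSize, seqs, "*", "RG:Z:1", sep = "\t")
  pos <- c(fwdPos, revPos)
  lines <- c(fwd, rev)[order(rep(records$contig, 2L), pos)]
  writeLines(c(hdr, lines), path)
  invisible(path)
}
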