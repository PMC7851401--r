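# Genotype reporting and VCF 4.2 emission.

#' @importFrom GenomicRanges GRanges start end width seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' PHRED-scale a genotype likelihood triple and call the genotype
#'
#' Converts mean natural-log genotype likelihoods to PHRED-scaled
#' likelihoods (PL = -10 log10 L) normalised so that the best genotype has
#' PL 0, calls the genotype with the smallest PL (ties give a missing
#' genotype), and reports the genotype quality as the gap between the two
#' smallest PL values.
#'
#' @param logLik numeric vector of length 3: natural-log likelihoods of
#'   genotypes 0/0, 0/1, 1/1.
#' @return list with integer \code{PL} (length 3), character \code{GT} and
#'   integer \code{GQ}.
#' @examples
#' phredAndGenotype(log(c(1, 1e-3, 1e-6)))  # PL 0/30/60, GT "0/0", GQ 30
#' @export
phredAndGenotype <- function(logLik) {
  stopifnot(length(logLik) == 3L, all(is.finite(logLik)))
  raw <- -10 * logLik / log(10)
  pl <- as.integer(round(raw - min(raw)))
  best <- which(pl == min(pl))
  gt <- if (length(best) > 1L) "./." else c("0/0", "0/1", "1/1")[best]
  gq <- as.integer(sort(pl)[2L] - sort(pl)[1L])
  list(PL = pl, GT = gt, GQ = gq)
}

#' Genotyping skip rule
#'
#' A sample is not genotyped at a locus when it has too little data
#' (fewer than \code{minPairs} read pairs) or much higher than average
#' coverage (more than \code{coverageMult} times the cohort median pair
#' count), which typically flags collapsed repeats.
#'
#' @param pairCount numeric vector: per-sample read-pair counts at the
#'   locus.
#' @param config a \code{\link{jdConfig}}.
#' @return logical vector: \code{TRUE} where the sample must be skipped
#'   (genotype reported as "./.").
#' @export
genotypeSkipRule <- function(pairCount, config = jdConfig()) {
  med <- median(pairCount)
  pairCount < config$minPairs |
    (med > 0 & pairCount > config$coverageMult * med)
}

# merged-call data.frame -> DeletionCallSet
makeCallSet <- function(merged, seqlengths, sampleIds, config = jdConfig()) {
  n <- nrow(merged)
  ns <- length(sampleIds)
  GT <- matrix("./.", n, ns)
  PL <- array(0L, dim = c(n, ns, 3L))
  GQ <- matrix(0L, n, ns)
  PC <- matrix(0, n, ns)
  af <- numeric(n)
  for (i in seq_len(n)) {
    ll <- merged$logLik[[i]]
    pc <- merged$pairCount[[i]]
    skip <- genotypeSkipRule(pc, config)
    altAlleles <- 0L
    calledAlleles <- 0L
    for (s in seq_len(ns)) {
      pg <- phredAndGenotype(ll[s, ])
      PL[i, s, ] <- pg$PL
      GQ[i, s] <- pg$GQ
      GT[i, s] <- if (skip[s]) "./." else pg$GT
      if (GT[i, s] != "./.") {
        calledAlleles <- calledAlleles + 2L
        altAlleles <- altAlleles +
          c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[[GT[i, s]]]
      }
    }
    PC[i, ] <- pc
    af[i] <- if (calledAlleles > 0L) altAlleles / calledAlleles else 0
  }
  lens <- as.integer(round(merged$len))
  gr <- GRanges(
    seqnames = names(seqlengths)[merged$contig],
    ranges = IRanges(start = merged$start + 1L, width = pmax(lens, 1L)),
    seqlengths = seqlengths)
  mcols(gr) <- DataFrame(svlen = -lens, af = af, stat = merged$stat,
                         nWindows = merged$nWindows)
  colnames(GT) <- colnames(GQ) <- colnames(PC) <- sampleIds
  new("DeletionCallSet", rowRanges = gr, sampleIds = sampleIds,
      GT = GT, PL = PL, GQ = GQ, pairCount = PC)
}

#' Write deletion calls as a multi-sample VCF 4.2 file
#'
#' Emits one \code{<DEL>} record per call with INFO fields END, SVLEN
#' (negative), SVTYPE and AF, FORMAT GT:PL:GQ and contig header lines from
#' the sequence dictionary. Positions are converted to the 1-based VCF
#' convention.
#'
#' @param callSet a \code{\link{DeletionCallSet}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeDeletionVcf <- function(callSet, file) {
  stopifnot(is(callSet, "DeletionCallSet"))
  gr <- callSet@rowRanges
  if (length(gr) > 1L) {
    o <- order(as.integer(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr))) stop("calls must be sorted by (contig, start)")
  }
  sl <- GenomeInfoDb::seqlengths(gr)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=joindel",
    '##ALT=<ID=DEL,Description="Deletion">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant (negative for deletions)">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Deletion allele frequency among genotyped alleles">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Normalized PHRED-scaled genotype likelihoods">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callSet@sampleIds), collapse = "\t"))
  lines <- hdr
  n <- length(gr)
  if (n) {
    pos <- start(gr)
    len <- -mcols(gr)$svlen
    info <- sprintf("END=%d;SVLEN=%d;SVTYPE=DEL;AF=%g",
                    pos + len, -len, mcols(gr)$af)
    recs <- character(n)
    for (i in seq_len(n)) {
      fields <- sprintf("%s:%s:%d", callSet@GT[i, ],
                        apply(callSet@PL[i, , , drop = FALSE], 2L,
                              function(x) paste(x, collapse = ",")),
                        callSet@GQ[i, ])
      recs[i] <- paste(c(as.character(seqnames(gr)[i]), pos[i],
                         sprintf("DEL%05d", i), "N", "<DEL>", ".", "PASS",
                         info[i], "GT:PL:GQ", fields), collapse = "\t")
    }
    lines <- c(lines, recs)
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a deletion VCF written by \code{\link{writeDeletionVcf}}
#'
#' Light-weight parser for the multi-sample deletion VCF produced by this
#' package (or any VCF restricted to symbolic \code{<DEL>} records with
#' GT/PL/GQ fields); the inverse of \code{\link{writeDeletionVcf}}.
#'
#' @param file VCF path.
#' @return a \code{\link{DeletionCallSet}}.
#' @export
readDeletionVcf <- function(file) {
  lines <- readLines(file)
  ct <- grep("^##contig=", lines, value = TRUE)
  nms <- sub('.*ID=([^,>]+).*', "\\1", ct)
  lens <- as.integer(sub(".*length=([0-9]+).*", "\\1", ct))
  sl <- setNames(lens, nms)
  hi <- grep("^#CHROM", lines)
  if (!length(hi)) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(lines[hi], "\t")[[1]]
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
  body <- lines[-seq_len(hi)]
  body <- body[nzchar(body)]
  n <- length(body)
  ns <- length(samples)
  GT <- matrix("./.", n, ns)
  PL <- array(0L, dim = c(n, ns, 3L))
  GQ <- matrix(0L, n, ns)
  contig <- character(n)
  pos <- integer(n)
  len <- integer(n)
  af <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t")[[1]]
    contig[i] <- f[1]
    pos[i] <- as.integer(f[2])
    info <- f[8]
    len[i] <- abs(as.integer(sub(".*SVLEN=(-?[0-9]+).*", "\\1", info)))
    af[i] <- if (grepl("AF=", info))
      as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1", info)) else NA_real_
    if (ns) {
      fmt <- strsplit(f[9], ":")[[1]]
      gi <- match(c("GT", "PL", "GQ"), fmt)
      for (s in seq_len(ns)) {
        parts <- strsplit(f[9L + s], ":")[[1]]
        GT[i, s] <- parts[gi[1]]
        if (!is.na(gi[2]))
          PL[i, s, ] <- as.integer(strsplit(parts[gi[2]], ",")[[1]])
        if (!is.na(gi[3])) GQ[i, s] <- as.integer(parts[gi[3]])
      }
    }
  }
  if (!length(sl)) {
    sl <- setNames(rep(NA_integer_, length(unique(contig))), unique(contig))
  }
  gr <- GRanges(contig, IRanges(start = pos, width = pmax(len, 1L)),
                seqlengths = sl)
  mcols(gr) <- DataFrame(svlen = -len, af = af,
                         stat = rep(NA_real_, n), nWindows = rep(NA_integer_, n))
  colnames(GT) <- colnames(GQ) <- samples
  new("DeletionCallSet", rowRanges = gr, sampleIds = samples,
      GT = GT, PL = PL, GQ = GQ,
      pairCount = matrix(NA_real_, n, ns, dimnames = list(NULL, samples)))
}
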