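# Profiling: reduce a coordinate-sorted alignment file to a compact
# insert-size profile with per-read-group null distributions.

# reference-consumed width of a CIGAR (M, D, N, =, X)
cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# leading / trailing soft+hard clip lengths of a CIGAR
cigarClips <- function(cigar) {
  left <- integer(length(cigar))
  hasL <- grepl("^[0-9]+[SH]", cigar)
  left[hasL] <- as.integer(sub("^([0-9]+)[SH].*", "\\1", cigar[hasL]))
  right <- integer(length(cigar))
  hasR <- grepl("[0-9]+[SH]$", cigar)
  right[hasR] <- as.integer(sub(".*?([0-9]+)[SH]$", "\\1", cigar[hasR]))
  # a hard clip outside a soft clip (e.g. 5H10S...) counts both
  lead2 <- regmatches(cigar, regexpr("^([0-9]+[SH]){2}", cigar))
  if (length(lead2)) {
    idx <- grepl("^([0-9]+[SH]){2}", cigar)
    left[idx] <- vapply(lead2, function(x)
      sum(as.integer(regmatches(x, gregexpr("[0-9]+", x))[[1]])), integer(1))
  }
  tail2 <- grepl("([0-9]+[SH]){2}$", cigar)
  if (any(tail2)) {
    m <- regmatches(cigar[tail2], regexpr("([0-9]+[SH]){2}$", cigar[tail2]))
    right[tail2] <- vapply(m, function(x)
      sum(as.integer(regmatches(x, gregexpr("[0-9]+", x))[[1]])), integer(1))
  }
  data.frame(left = left, right = right)
}

#' Clip-extended insert size of a read pair
#'
#' The insert size is the distance from the leftmost alignment position of
#' the forward read to the rightmost alignment position of the reverse read,
#' each extended by any clipped bases. Coordinates are 0-based half-open, so
#' a 300 bp fragment with fully aligned reads yields 300.
#'
#' @param fwdStart 0-based leftmost aligned position of the forward read.
#' @param revEnd 0-based exclusive rightmost aligned position of the reverse
#'   read (i.e. one past its last aligned base).
#' @param fwdLeftClip clipped bases on the left of the forward read.
#' @param revRightClip clipped bases on the right of the reverse read.
#' @return integer insert size in bp; \code{NA} for non-positive results
#'   (the pair is filtered, not an error). Vectorised.
#' @examples
#' computeInsertSize(1000, 1300)          # 300
#' computeInsertSize(1000, 1300, 5, 10)   # 315
#' computeInsertSize(0, 0)                # NA (rejected)
#' @export
computeInsertSize <- function(fwdStart, revEnd, fwdLeftClip = 0L, revRightClip = 0L) {
  ins <- as.integer((revEnd + revRightClip) - (fwdStart - fwdLeftClip))
  ins[ins < 1L] <- NA_integer_
  ins
}

#' Per-alignment confidence filter
#'
#' Decides whether a single alignment record may contribute to a profile:
#' paired, both mates mapped to the same contig, opposite strands, primary
#' (not secondary/supplementary), not a duplicate or QC failure, and mapping
#' quality at least \code{config$minMapq}.
#'
#' @param aln a list or data.frame with elements \code{flag}, \code{mapq},
#'   and optionally \code{rname} and \code{mrnm} (mate contig; \code{"="} or
#'   \code{NA} mean same contig).
#' @param config a \code{\link{jdConfig}}.
#' @return logical (vectorised over rows).
#' @export
passesQualityFilters <- function(aln, config = jdConfig()) {
  flag <- as.integer(aln$flag)
  mapq <- as.integer(aln$mapq)
  ok <- bitwAnd(flag, 1L) != 0L &                     # paired
    bitwAnd(flag, 4L) == 0L &                         # mapped
    bitwAnd(flag, 8L) == 0L &                         # mate mapped
    bitwAnd(flag, 256L + 512L + 1024L + 2048L) == 0L &
    (bitwAnd(flag, 16L) != 0L) != (bitwAnd(flag, 32L) != 0L) &  # FR-compatible
    !is.na(mapq) & mapq >= config$minMapq
  if (!is.null(aln$mrnm) && !is.null(aln$rname)) {
    same <- is.na(aln$mrnm) | aln$mrnm == "=" | aln$mrnm == aln$rname
    ok <- ok & same
  }
  ok & !is.na(ok)
}

#' Build an insert-size histogram
#'
#' @param insertSizes integer vector of insert sizes (bp, >= 1).
#' @param readGroup integer read-group id.
#' @return an \code{\link{InsertSizeHistogram}}.
#' @export
newInsertSizeHistogram <- function(insertSizes, readGroup = 1L) {
  insertSizes <- as.integer(insertSizes)
  stopifnot(length(insertSizes) > 0L, all(insertSizes >= 1L))
  off <- min(insertSizes)
  counts <- tabulate(insertSizes - off + 1L, nbins = max(insertSizes) - off + 1L)
  tot <- length(insertSizes)
  m <- mean(insertSizes)
  s <- if (tot > 1L) sqrt(sum((insertSizes - m)^2) / tot) else 0
  new("InsertSizeHistogram", counts = as.numeric(counts), offset = as.integer(off),
      mean = m, sd = s, total = as.numeric(tot), readGroup = as.integer(readGroup))
}

#' Default null-sampling regions
#'
#' When no sampling BED is supplied, the null insert-size distribution is
#' estimated from the middle 60 percent of each contig, which avoids
#' telomeric/centromere-proximal contig ends.
#'
#' @param seqlengths named integer vector (contig -> length).
#' @return a data.frame with columns \code{contig}, \code{start}, \code{end}
#'   (0-based half-open).
#' @export
defaultSamplingRegions <- function(seqlengths) {
  data.frame(
    contig = names(seqlengths),
    start = as.integer(floor(0.2 * seqlengths)),
    end = as.integer(ceiling(0.8 * seqlengths)),
    stringsAsFactors = FALSE
  )
}

#' Estimate the null insert-size distribution
#'
#' Builds one \code{InsertSizeHistogram} per read group from filtered read
#' pairs whose forward read starts inside a sampling region, up to
#' \code{config$maxSamplePairs} pairs per read group. The histogram support
#' is capped at mean + \code{config$histInsertCapSd} standard deviations.
#'
#' @param records data.frame of read-pair records (columns \code{contig},
#'   \code{fwdStart}, \code{insertSize}, \code{readGroup}); \code{contig} is
#'   a 1-based index into \code{seqlengths}.
#' @param seqlengths named integer vector (sequence dictionary).
#' @param samplingRegions data.frame \code{contig}/\code{start}/\code{end}
#'   (0-based half-open) or NULL for \code{\link{defaultSamplingRegions}}.
#' @param config a \code{\link{jdConfig}}.
#' @return named list of \code{InsertSizeHistogram}, one per read group.
#' @export
estimateNullDistribution <- function(records, seqlengths,
                                     samplingRegions = NULL,
                                     config = jdConfig()) {
  if (is.null(samplingRegions))
    samplingRegions <- defaultSamplingRegions(seqlengths)
  if (nrow(samplingRegions) == 0L)
    stop("sampling regions are empty")
  unknown <- setdiff(unique(samplingRegions$contig), names(seqlengths))
  if (length(unknown))
    stop("sampling regions on contigs absent from the sequence dictionary: ",
         paste(unknown, collapse = ", "))
  regIdx <- match(samplingRegions$contig, names(seqlengths))
  inside <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(samplingRegions))) {
    inside <- inside | (records$contig == regIdx[i] &
                          records$fwdStart >= samplingRegions$start[i] &
                          records$fwdStart < samplingRegions$end[i])
  }
  sampled <- records[inside, , drop = FALSE]
  groups <- sort(unique(records$readGroup))
  hists <- vector("list", length(groups))
  names(hists) <- as.character(groups)
  for (g in seq_along(groups)) {
    ins <- sampled$insertSize[sampled$readGroup == groups[g]]
    if (length(ins) > config$maxSamplePairs)
      ins <- ins[seq_len(config$maxSamplePairs)]
    if (length(ins) < config$minSamplePairs)
      stop(sprintf(
        "insufficient data for null distribution: read group %s has %d sampled pairs (minimum %d)",
        groups[g], length(ins), config$minSamplePairs))
    # support cap on a robust location/scale: sampling regions can contain
    # genuine deletions whose spanning pairs must not inflate the null
    ctr <- median(ins)
    sc <- max(mad(ins), 1)
    cap <- ctr + config$histInsertCapSd * sc
    ins <- ins[ins <= cap]
    if (length(ins) < config$minSamplePairs)
      stop(sprintf(
        "insufficient data for null distribution: read group %s has %d pairs after support capping (minimum %d)",
        groups[g], length(ins), config$minSamplePairs))
    hists[[g]] <- newInsertSizeHistogram(ins, readGroup = groups[g])
  }
  hists
}

#' Assemble a read-pair profile from records
#'
#' Sorts the records, estimates the per-read-group null distributions from
#' the sampling regions, and returns the profile.
#'
#' @inheritParams estimateNullDistribution
#' @param sampleId sample name.
#' @param readLen representative clip-extended read length in bp.
#' @return a \code{\link{ReadPairProfile}}.
#' @export
buildProfile <- function(records, seqlengths, sampleId,
                         samplingRegions = NULL, config = jdConfig(),
                         readLen = 150L) {
  records <- records[order(records$contig, records$fwdStart), , drop = FALSE]
  rownames(records) <- NULL
  if (is.finite(config$recordInsertCap))
    records <- records[records$insertSize <= config$recordInsertCap, , drop = FALSE]
  hists <- estimateNullDistribution(records, seqlengths, samplingRegions, config)
  new("ReadPairProfile",
      sampleId = as.character(sampleId),
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)),
      histograms = hists,
      records = records,
      readLen = as.integer(readLen))
}

#' Profile a coordinate-sorted BAM/SAM file
#'
#' Reads the alignments of one sample, keeps confidently aligned FR read
#' pairs (see \code{\link{passesQualityFilters}}), computes clip-extended
#' insert sizes and reduces everything to a \code{\link{ReadPairProfile}}.
#' SAM input is converted on the fly via \code{Rsamtools::asBam}.
#'
#' @param file path to a coordinate-sorted BAM (or plain SAM) file.
#' @param sampleId sample name; defaults to the file base name.
#' @param samplingRegions optional data.frame of null-sampling regions
#'   (\code{contig}, 0-based \code{start}, \code{end}).
#' @param config a \code{\link{jdConfig}}.
#' @return a \code{\link{ReadPairProfile}}.
#' @export
profileBam <- function(file, sampleId = NULL, samplingRegions = NULL,
                       config = jdConfig()) {
  if (!file.exists(file)) stop("no such file: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.bam$", "", basename(file), ignore.case = TRUE)
  hdr <- Rsamtools::scanBamHeader(file)[[1]]
  sq <- hdr$targets
  if (length(sq) == 0L) stop("BAM header has no sequence dictionary")
  hd <- unlist(hdr$text[names(hdr$text) == "@HD"])
  so <- grep("^SO:", hd, value = TRUE)
  if (length(so) && !grepl("coordinate", so[1]))
    stop("input is not coordinate-sorted (", so[1], ")")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "RG")
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  rg <- b$tag$RG
  if (is.null(rg)) rg <- rep("1", length(b$qname))
  rg[is.na(rg)] <- "1"
  aln <- data.frame(
    qname = b$qname, flag = b$flag, rname = as.character(b$rname),
    pos = b$pos, mapq = b$mapq, cigar = b$cigar, rg = rg,
    stringsAsFactors = FALSE)
  bad <- is.na(aln$pos) | is.na(aln$cigar) | aln$cigar == "*"
  if (any(bad)) {
    warning(sum(bad), " unparseable alignment record(s) skipped")
    aln <- aln[!bad, , drop = FALSE]
  }
  keep <- passesQualityFilters(aln, config)
  aln <- aln[keep, , drop = FALSE]
  # pair mates by query name
  cnt <- table(aln$qname)
  aln <- aln[aln$qname %in% names(cnt)[cnt == 2L], , drop = FALSE]
  if (nrow(aln)) {
    rev <- bitwAnd(aln$flag, 16L) != 0L
    o <- order(aln$qname, rev)            # forward mate first within pair
    aln <- aln[o, , drop = FALSE]
    fwd <- aln[seq(1L, nrow(aln), by = 2L), , drop = FALSE]
    rvs <- aln[seq(2L, nrow(aln), by = 2L), , drop = FALSE]
    ok <- fwd$rname == rvs$rname &
      bitwAnd(fwd$flag, 16L) == 0L & bitwAnd(rvs$flag, 16L) != 0L
    fwd <- fwd[ok & !is.na(ok), , drop = FALSE]
    rvs <- rvs[ok & !is.na(ok), , drop = FALSE]
    fc <- cigarClips(fwd$cigar)
    rc <- cigarClips(rvs$cigar)
    fwdStart0 <- fwd$pos - 1L             # SAM POS is 1-based
    revEnd0 <- rvs$pos - 1L + cigarRefWidth(rvs$cigar)
    ins <- computeInsertSize(fwdStart0, revEnd0, fc$left, rc$right)
    proper <- !is.na(ins) & fwdStart0 <= revEnd0
    rgIds <- sort(unique(fwd$rg))
    records <- data.frame(
      contig = match(fwd$rname, names(sq)),
      fwdStart = as.integer(fwdStart0),
      insertSize = ins,
      readGroup = match(fwd$rg, rgIds))[proper, , drop = FALSE]
    readLen <- as.integer(round(median(
      cigarRefWidth(fwd$cigar) + fc$left + fc$right, na.rm = TRUE)))
  } else {
    records <- data.frame(contig = integer(), fwdStart = integer(),
                          insertSize = integer(), readGroup = integer())
    readLen <- 150L
  }
  buildProfile(records, setNames(as.integer(sq), names(sq)), sampleId,
               samplingRegions = samplingRegions, config = config,
               readLen = readLen)
}
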