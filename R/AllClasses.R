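#' @import methods
#' @importFrom stats median mad quantile rnorm runif rbinom rpois qchisq setNames
#' @importFrom utils head tail
NULL

#' Insert-size histogram of one read group
#'
#' Counts of clip-extended insert sizes observed for the confidently aligned
#' read pairs of a single read group, together with summary moments. The
#' histogram describes the null (reference) distribution of insert sizes for
#' the sample and is the basis for all window likelihood computations.
#'
#' @slot counts numeric vector of counts; element \code{i} is the number of
#'   pairs with insert size \code{offset + i - 1} bp.
#' @slot offset integer, insert size (bp) of the first element of
#'   \code{counts}.
#' @slot mean numeric, mean insert size (bp).
#' @slot sd numeric, standard deviation of the insert size (bp).
#' @slot total numeric, total number of pairs in the histogram.
#' @slot readGroup integer read-group id.
#' @export
setClass("InsertSizeHistogram",
  representation(
    counts = "numeric",
    offset = "integer",
    mean = "numeric",
    sd = "numeric",
    total = "numeric",
    readGroup = "integer"
  )
)

setValidity("InsertSizeHistogram", function(object) {
  msg <- character()
  if (length(object@counts) == 0L)
    msg <- c(msg, "histogram has no counts")
  if (any(object@counts < 0))
    msg <- c(msg, "negative counts")
  if (abs(sum(object@counts) - object@total) > 1e-6)
    msg <- c(msg, "total does not match sum of counts")
  if (object@total > 0) {
    sizes <- object@offset + seq_along(object@counts) - 1L
    m <- sum(sizes * object@counts) / object@total
    if (abs(m - object@mean) > 1e-6)
      msg <- c(msg, "mean not recomputable from counts")
  }
  if (length(msg)) msg else TRUE
})

#' Read-pair profile of one sample
#'
#' Compact per-sample reduction of a coordinate-sorted alignment file:
#' one record per confidently aligned read pair (contig, forward-read start,
#' clip-extended insert size, read group), the null insert-size histogram of
#' each read group, and the sequence dictionary. Records are sorted by
#' (contig, forward start) so that genomic positions can be sought
#' efficiently; on disk the format carries a positional index
#' (see \code{\link{writeProfile}}).
#'
#' @slot sampleId character scalar.
#' @slot seqlengths named integer vector: the sequence dictionary
#'   (contig name -> length in bp), in dictionary order.
#' @slot histograms list of \code{InsertSizeHistogram}, one per read group,
#'   named by read-group id.
#' @slot records data.frame with integer columns \code{contig} (1-based index
#'   into the dictionary), \code{fwdStart} (0-based leftmost position of the
#'   forward read), \code{insertSize} (bp, >= 1), \code{readGroup}.
#' @slot readLen integer, representative (median) clip-extended read length,
#'   used to recover forward-read end positions during start estimation.
#' @export
setClass("ReadPairProfile",
  representation(
    sampleId = "character",
    seqlengths = "integer",
    histograms = "list",
    records = "data.frame",
    readLen = "integer"
  )
)

setValidity("ReadPairProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (is.null(names(object@seqlengths)))
    msg <- c(msg, "seqlengths must be named (contig names)")
  r <- object@records
  need <- c("contig", "fwdStart", "insertSize", "readGroup")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else if (nrow(r)) {
    if (any(r$insertSize < 1L)) msg <- c(msg, "insertSize must be >= 1")
    if (any(r$fwdStart < 0L)) msg <- c(msg, "fwdStart must be >= 0")
    o <- order(r$contig, r$fwdStart)
    if (!identical(o, seq_len(nrow(r))))
      msg <- c(msg, "records must be sorted by (contig, fwdStart)")
    if (any(r$contig < 1L) || any(r$contig > length(object@seqlengths)))
      msg <- c(msg, "record contig index outside sequence dictionary")
    if (!all(as.character(r$readGroup) %in% names(object@histograms)))
      msg <- c(msg, "every record read group needs a histogram")
  }
  if (length(msg)) msg else TRUE
})

#' Window-transformed insert-size deviation likelihood
#'
#' The per-read-group null histogram transformed to the relative likelihood
#' H(delta) of observing a read pair with insert-size deviation delta
#' overlapping a window of size w. Length-weighted (a longer fragment can
#' overlap more window placements), renormalised to sum 1 and floored so
#' that likelihood products never hit zero.
#'
#' @slot probs numeric vector of probabilities over consecutive integer
#'   deviations.
#' @slot deltaMin integer deviation (bp) of the first element of
#'   \code{probs}.
#' @slot floor numeric, probability returned for deviations outside the
#'   support (and lower bound inside it).
#' @export
setClass("WindowHistogram",
  representation(
    probs = "numeric",
    deltaMin = "integer",
    floor = "numeric"
  )
)

setValidity("WindowHistogram", function(object) {
  msg <- character()
  if (any(object@probs < object@floor * (1 - 1e-12)))
    msg <- c(msg, "probabilities below floor")
  if (object@floor <= 0)
    msg <- c(msg, "floor must be positive")
  if (length(msg)) msg else TRUE
})

#' Set of merged deletion calls with genotypes
#'
#' Container produced by the joint caller: one row per nonredundant deletion
#' (a \code{GRanges} holding position, length and cohort statistics) plus
#' per-sample genotype information (called genotype, PHRED-scaled genotype
#' likelihoods, genotype quality, supporting pair counts).
#'
#' @slot rowRanges \code{GRanges} of the deletions (1-based, width = deletion
#'   length); metadata columns \code{svlen}, \code{af}, \code{stat}
#'   (the -2 log Lambda test statistic, maximum over merged windows).
#' @slot sampleIds character vector of sample names (column order of the
#'   matrices).
#' @slot GT character matrix calls x samples with values "0/0", "0/1",
#'   "1/1" or "./.".
#' @slot PL integer array calls x samples x 3 of normalised PHRED-scaled
#'   genotype likelihoods.
#' @slot GQ integer matrix calls x samples.
#' @slot pairCount numeric matrix calls x samples: read pairs informing the
#'   genotype at the locus.
#' @export
setClass("DeletionCallSet",
  representation(
    rowRanges = "GRanges",
    sampleIds = "character",
    GT = "matrix",
    PL = "array",
    GQ = "matrix",
    pairCount = "matrix"
  )
)

setValidity("DeletionCallSet", function(object) {
  msg <- character()
  n <- length(object@rowRanges)
  s <- length(object@sampleIds)
  if (!identical(dim(object@GT), c(n, s)))
    msg <- c(msg, "GT dimensions do not match calls x samples")
  if (!identical(dim(object@PL), c(n, s, 3L)))
    msg <- c(msg, "PL must be calls x samples x 3")
  if (!identical(dim(object@GQ), c(n, s)))
    msg <- c(msg, "GQ dimensions do not match calls x samples")
  ok <- object@GT %in% c("0/0", "0/1", "1/1", "./.")
  if (!all(ok)) msg <- c(msg, "invalid genotype strings")
  if (length(msg)) msg else TRUE
})

#' Simulated cohort of diploid genomes
#'
#' A deletion set together with sampled haplotypes combined into diploid
#' individuals. Genotypes are the sums of the two haplotype indicators.
#'
#' @slot deletions \code{GRanges} of true deletions with metadata column
#'   \code{af} (population allele frequency).
#' @slot genotypes integer matrix samples x deletions with values 0/1/2.
#' @slot haplotypes logical matrix (2*samples) x deletions; rows 2i-1 and 2i
#'   are the two haplotypes of sample i.
#' @slot seed integer seed the cohort was drawn with.
#' @export
setClass("SimCohort",
  representation(
    deletions = "GRanges",
    genotypes = "matrix",
    haplotypes = "matrix",
    seed = "integer"
  )
)

setValidity("SimCohort", function(object) {
  msg <- character()
  h <- object@haplotypes
  g <- object@genotypes
  if (nrow(h) != 2L * nrow(g))
    msg <- c(msg, "haplotype rows must be twice the sample count")
  if (ncol(h) != ncol(g) || ncol(g) != length(object@deletions))
    msg <- c(msg, "deletion dimension mismatch")
  if (nrow(g)) {
    gg <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
      h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
    if (!all(gg == g))
      msg <- c(msg, "genotypes must equal haplotype sums")
  }
  if (length(msg)) msg else TRUE
})
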