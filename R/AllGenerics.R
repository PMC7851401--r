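#' @rdname ReadPairProfile-class
#' @param object a \code{ReadPairProfile}
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname ReadPairProfile-class
#' @export
setGeneric("profileRecords", function(object) standardGeneric("profileRecords"))

#' @rdname ReadPairProfile-class
#' @export
setGeneric("histograms", function(object) standardGeneric("histograms"))

#' @rdname ReadPairProfile-class
#' @export
setGeneric("seqDict", function(object) standardGeneric("seqDict"))

#' @rdname DeletionCallSet-class
#' @param object a \code{DeletionCallSet}
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))

#' @rdname DeletionCallSet-class
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname DeletionCallSet-class
#' @export
setGeneric("genotypeQuality", function(object) standardGeneric("genotypeQuality"))

#' @rdname DeletionCallSet-class
#' @export
setGeneric("phredLikelihoods", function(object) standardGeneric("phredLikelihoods"))

#' @rdname DeletionCallSet-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname SimCohort-class
#' @param object a \code{SimCohort}
#' @export
setGeneric("trueDeletions", function(object) standardGeneric("trueDeletions"))

setMethod("sampleId", "ReadPairProfile", function(object) object@sampleId)
setMethod("profileRecords", "ReadPairProfile", function(object) object@records)
setMethod("histograms", "ReadPairProfile", function(object) object@histograms)
setMethod("seqDict", "ReadPairProfile", function(object) object@seqlengths)

setMethod("calls", "DeletionCallSet", function(object) object@rowRanges)
setMethod("genotypes", "DeletionCallSet", function(object) object@GT)
setMethod("genotypeQuality", "DeletionCallSet", function(object) object@GQ)
setMethod("phredLikelihoods", "DeletionCallSet", function(object) object@PL)
setMethod("sampleIds", "DeletionCallSet", function(object) object@sampleIds)

setMethod("trueDeletions", "SimCohort", function(object) object@deletions)
setMethod("genotypes", "SimCohort", function(object) object@genotypes)

setMethod("show", "InsertSizeHistogram", function(object) {
  cat(sprintf(
    "InsertSizeHistogram | read group %d | n = %g | mean = %.2f bp | sd = %.2f bp | support [%d, %d]\n",
    object@readGroup, object@total, object@mean, object@sd,
    object@offset, object@offset + length(object@counts) - 1L
  ))
})

setMethod("show", "ReadPairProfile", function(object) {
  cat(sprintf(
    "ReadPairProfile '%s': %d read pairs on %d contig(s), %d read group(s), read length %d bp\n",
    object@sampleId, nrow(object@records), length(object@seqlengths),
    length(object@histograms), object@readLen
  ))
  for (h in object@histograms) show(h)
})

setMethod("show", "WindowHistogram", function(object) {
  cat(sprintf(
    "WindowHistogram over deviations [%d, %d] bp (floor %g)\n",
    object@deltaMin, object@deltaMin + length(object@probs) - 1L, object@floor
  ))
})

setMethod("show", "DeletionCallSet", function(object) {
  cat(sprintf(
    "DeletionCallSet: %d deletion(s) x %d sample(s)\n",
    length(object@rowRanges), length(object@sampleIds)
  ))
  if (length(object@rowRanges)) show(object@rowRanges)
})

setMethod("show", "SimCohort", function(object) {
  cat(sprintf(
    "SimCohort: %d diploid sample(s), %d simulated deletion(s) (seed %d)\n",
    nrow(object@genotypes), length(object@deletions), object@seed
  ))
})
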