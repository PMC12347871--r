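#' @name accessors
#' @title Accessors for cmaMRD objects
#' @param x a cmaMRD object.
#' @description Small accessor generics: \code{sampleIds} returns the sample
#'   identifiers carried by an object, \code{featureIds} the
#'   \code{"SYMBOL:event"} feature identifiers of a
#'   \linkS4class{GeneEventMatrix}, \code{presenceMatrix} its binary
#'   features-by-samples assay, \code{segmentSizeKb} segment sizes in kb
#'   ((end - start + 1)/1000, 1-based inclusive), \code{pValue} and
#'   \code{nullAccuracies} the components of a
#'   \linkS4class{PermutationResult}, and \code{assignments} /
#'   \code{matchQuality} those of a \linkS4class{MatchedReference}.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname accessors
#' @export
setGeneric("segmentSizeKb", function(x) standardGeneric("segmentSizeKb"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nullAccuracies", function(x) standardGeneric("nullAccuracies"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("matchQuality", function(x) standardGeneric("matchQuality"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "AberrationCalls",
          function(x) unique(S4Vectors::mcols(x)$sample_id))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GeneEventMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("featureIds", "GeneEventMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("presenceMatrix", "GeneEventMatrix",
          function(x) SummarizedExperiment::assay(x, "presence"))

#' @rdname accessors
#' @export
setMethod("segmentSizeKb", "GRanges",
          function(x) GenomicRanges::width(x) / 1000)

#' @rdname accessors
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("nullAccuracies", "PermutationResult", function(x) x@nulls)

#' @rdname accessors
#' @export
setMethod("assignments", "MatchedReference", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("matchQuality", "MatchedReference", function(x) x@quality)

#' Observed accuracy of a permutation test
#' @param x a \linkS4class{PermutationResult}.
#' @return numeric observed cross-validated accuracy.
#' @export
observedAccuracy <- function(x) {
  stopifnot(is(x, "PermutationResult"))
  x@observed
}

setMethod("show", "AberrationCalls", function(object) {
  cat(sprintf("AberrationCalls: %d segment(s), %d sample(s)\n",
              length(object), length(sampleIds(object))))
  if (length(object)) {
    tab <- table(S4Vectors::mcols(object)$event_type)
    cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  methods::callNextMethod()
})

setMethod("show", "GeneEventMatrix", function(object) {
  cat(sprintf("GeneEventMatrix: %d feature(s) x %d sample(s); density %.3f\n",
              nrow(object), ncol(object),
              if (length(object)) mean(presenceMatrix(object)) else NA_real_))
  methods::callNextMethod()
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed accuracy %.4f, %d permutation(s), p = %.4g\n",
    object@observed, length(object@nulls), object@pValue))
  cat(sprintf("  null accuracies: min %.3f / median %.3f / max %.3f\n",
              min(object@nulls), stats::median(object@nulls),
              max(object@nulls)))
})

setMethod("show", "MatchedReference", function(object) {
  cat(sprintf(
    "MatchedReference: %d patient(s) x 3 references, mean |age diff| %.2f y\n",
    length(unique(object@assignments$patient_id)), object@quality))
})

setMethod("show", "QCThresholds", function(object) {
  cat("QCThresholds:\n",
      sprintf("  markers >= %d (cnLOH) / %d (gain) / %d (loss)\n",
              object@minMarkersLoh, object@minMarkersGain,
              object@minMarkersLoss),
      sprintf("  |mean log2 ratio| > %.2f (gain/loss)\n",
              object@minAbsLog2Ratio),
      sprintf("  landscape size > %.0f kb (CNV) / %.0f kb (cnLOH)\n",
              object@minCnvKbLandscape, object@minLohKbLandscape))
})
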