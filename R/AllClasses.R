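## Central S4 data objects. AberrationCalls and GeneCatalog extend GRanges so
## all range machinery (findOverlaps, subsetting, seqnames/start/end) comes
## for free; validity pins down the metadata contract.

#' Segment-level CMA aberration calls
#'
#' A \linkS4class{GRanges} subclass holding one chromosomal-microarray call
#' per range, with mandatory metadata columns: \code{sample_id} (character),
#' \code{event_type} (one of \code{gain}, \code{loss}, \code{loss_mosaic},
#' \code{cnLOH}), \code{marker_count} (non-negative integer of SNP markers
#' supporting the call), \code{mean_log2ratio} (numeric; \code{NA} for cnLOH
#' segments, which are copy-neutral by definition), and
#' \code{mosaic_fraction} (fraction of cells carrying the event, in [0,1],
#' or \code{NA}). Coordinates are 1-based inclusive.
#'
#' @seealso \code{\link{readSegments}}, \code{\link{qcFilter}}
#' @export
setClass("AberrationCalls", contains = "GRanges")

setValidity("AberrationCalls", function(object) {
  mc <- S4Vectors::mcols(object)
  need <- c("sample_id", "event_type", "marker_count", "mean_log2ratio",
            "mosaic_fraction")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(GenomicRanges::start(object) < 1L))
    return("segment start coordinates must be >= 1 (1-based inclusive)")
  if (!all(mc$event_type %in% EVENT_TYPES))
    return(paste0("unknown event_type value(s): ",
                  paste(unique(setdiff(mc$event_type, EVENT_TYPES)),
                        collapse = ", ")))
  if (any(is.na(mc$marker_count)) || any(mc$marker_count < 0L))
    return("marker_count must be a non-negative integer")
  if (any(!is.na(mc$mean_log2ratio[mc$event_type == "cnLOH"])))
    return("cnLOH segments must not carry a mean_log2ratio (copy-neutral)")
  mf <- mc$mosaic_fraction
  if (any(!is.na(mf) & (mf < 0 | mf > 1)))
    return("mosaic_fraction must lie in [0, 1]")
  TRUE
})

#' Construct AberrationCalls from per-segment vectors
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome labels (e.g. \code{"chr19"}).
#' @param start,end 1-based inclusive coordinates.
#' @param event_type event types; folded case/punctuation-insensitively into
#'   the vocabulary \code{gain}, \code{loss}, \code{loss_mosaic},
#'   \code{cnLOH} (see \code{\link{parseEventType}}).
#' @param marker_count SNP marker counts (non-negative).
#' @param mean_log2ratio mean log2 ratios (\code{NA} for cnLOH).
#' @param mosaic_fraction mosaic fractions in [0,1] or \code{NA}.
#' @return An \linkS4class{AberrationCalls} object.
#' @export
AberrationCalls <- function(sample_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            event_type = character(),
                            marker_count = integer(),
                            mean_log2ratio = NA_real_,
                            mosaic_fraction = NA_real_) {
  n <- length(sample_id)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.numeric(start), end = as.numeric(end)),
    sample_id = as.character(sample_id),
    event_type = if (n) parseEventType(event_type) else character(),
    marker_count = as.integer(rep_len(marker_count, n)),
    mean_log2ratio = as.numeric(rep_len(mean_log2ratio, n)),
    mosaic_fraction = as.numeric(rep_len(mosaic_fraction, n)))
  methods::new("AberrationCalls", gr)
}

#' Gene catalog with cytoband annotation
#'
#' A \linkS4class{GRanges} subclass with one range per gene and metadata
#' columns \code{symbol} (unique gene symbols) and \code{band} (cytoband
#' label such as \code{"19q13.2"}). Internal coordinates are 1-based
#' inclusive; the on-disk BED-like interchange format is 0-based half-open
#' and is converted at the boundary by \code{\link{readGeneCatalog}}.
#'
#' @export
setClass("GeneCatalog", contains = "GRanges")

setValidity("GeneCatalog", function(object) {
  mc <- S4Vectors::mcols(object)
  miss <- setdiff(c("symbol", "band"), colnames(mc))
  if (length(miss))
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(mc$symbol))
    return(paste0("duplicate gene symbol(s): ",
                  paste(unique(mc$symbol[duplicated(mc$symbol)]),
                        collapse = ", ")))
  if (length(object) && any(GenomicRanges::start(object) < 1L))
    return("gene start coordinates must be >= 1 (1-based inclusive)")
  TRUE
})

#' @param symbol,chrom,start,end,band per-gene vectors (1-based inclusive
#'   coordinates).
#' @return A \linkS4class{GeneCatalog}.
#' @rdname GeneCatalog-class
#' @export
GeneCatalog <- function(symbol = character(), chrom = character(),
                        start = integer(), end = integer(),
                        band = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.numeric(start), end = as.numeric(end)),
    symbol = as.character(symbol),
    band = as.character(band))
  methods::new("GeneCatalog", gr)
}

#' Segment-validity and landscape-size thresholds
#'
#' QC thresholds for CMA calls. Marker-count minima are inclusive
#' (\code{>=}): 50 markers for cnLOH, 50 for duplications (gains), 20 for
#' deletions (losses). CNV validity additionally requires
#' \code{|mean_log2ratio| > min_abs_log2ratio} (default 0.25); cnLOH is
#' copy-neutral and has no log2-ratio criterion. The landscape size
#' thresholds are strict (\code{>}, "exceeding"): 500 kb for gains/losses
#' and 5000 kb for cnLOH, and apply only to landscape reporting, never to
#' feature encoding.
#'
#' @slot minMarkersLoh,minMarkersGain,minMarkersLoss integer marker-count
#'   minima per event class.
#' @slot minAbsLog2Ratio numeric absolute log2-ratio validity bound.
#' @slot minCnvKbLandscape,minLohKbLandscape numeric size cut-offs (kb) for
#'   landscape reporting.
#' @export
setClass("QCThresholds",
  representation(minMarkersLoh = "integer", minMarkersGain = "integer",
                 minMarkersLoss = "integer", minAbsLog2Ratio = "numeric",
                 minCnvKbLandscape = "numeric", minLohKbLandscape = "numeric"))

setValidity("QCThresholds", function(object) {
  vals <- c(object@minMarkersLoh, object@minMarkersGain, object@minMarkersLoss,
            object@minAbsLog2Ratio, object@minCnvKbLandscape,
            object@minLohKbLandscape)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all thresholds must be finite and > 0")
  TRUE
})

#' @param minMarkersLoh,minMarkersGain,minMarkersLoss,minAbsLog2Ratio,minCnvKbLandscape,minLohKbLandscape
#'   see slot documentation.
#' @rdname QCThresholds-class
#' @export
QCThresholds <- function(minMarkersLoh = 50L, minMarkersGain = 50L,
                         minMarkersLoss = 20L, minAbsLog2Ratio = 0.25,
                         minCnvKbLandscape = 500, minLohKbLandscape = 5000) {
  methods::new("QCThresholds",
    minMarkersLoh = as.integer(minMarkersLoh),
    minMarkersGain = as.integer(minMarkersGain),
    minMarkersLoss = as.integer(minMarkersLoss),
    minAbsLog2Ratio = as.numeric(minAbsLog2Ratio),
    minCnvKbLandscape = as.numeric(minCnvKbLandscape),
    minLohKbLandscape = as.numeric(minLohKbLandscape))
}

#' Binary gene-by-event feature matrix
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the presence/absence
#' encoding consumed by the classifier and the univariate statistics: rows
#' are \code{"SYMBOL:event"} features (rowData: \code{symbol}, \code{event}
#' in \{gain, loss, cnLOH\} — mosaic losses are merged into \code{loss} —
#' and \code{band}), columns are samples, and the single assay
#' \code{presence} contains exactly 0 or 1.
#'
#' @seealso \code{\link{encodeGeneEvents}}
#' @export
setClass("GeneEventMatrix", contains = "SummarizedExperiment")

setValidity("GeneEventMatrix", function(object) {
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'presence' is required")
  a <- SummarizedExperiment::assay(object, "presence")
  if (length(a) && !all(a %in% c(0L, 1L)))
    return("assay 'presence' must contain only 0 and 1")
  rd <- SummarizedExperiment::rowData(object)
  miss <- setdiff(c("symbol", "event"), colnames(rd))
  if (length(miss))
    return(paste0("missing rowData column(s): ", paste(miss, collapse = ", ")))
  if (length(rd$event) && !all(rd$event %in% c("gain", "loss", "cnLOH")))
    return("rowData event must be one of gain, loss, cnLOH")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    return("duplicate feature ids")
  TRUE
})

#' Random-forest and permutation-test settings
#'
#' @slot nFolds folds for stratified cross-validation (default 10).
#' @slot nTrees trees per forest (default 500).
#' @slot nPermutations label permutations for the null distribution
#'   (default 1000).
#' @slot topK features retained by \code{\link{rankFeatures}} (default 200).
#' @slot seed integer seed controlling fold assignment, forests and
#'   permutations.
#' @export
setClass("ModelConfig",
  representation(nFolds = "integer", nTrees = "integer",
                 nPermutations = "integer", topK = "integer",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (object@nFolds < 2L) return("nFolds must be >= 2")
  if (object@nPermutations < 1L) return("nPermutations must be >= 1")
  if (object@topK < 1L) return("topK must be >= 1")
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  TRUE
})

#' @param nFolds,nTrees,nPermutations,topK,seed see slot documentation.
#' @rdname ModelConfig-class
#' @export
ModelConfig <- function(nFolds = 10L, nTrees = 500L, nPermutations = 1000L,
                        topK = 200L, seed = 1L) {
  methods::new("ModelConfig", nFolds = as.integer(nFolds),
               nTrees = as.integer(nTrees),
               nPermutations = as.integer(nPermutations),
               topK = as.integer(topK), seed = as.integer(seed))
}

#' Permutation-test result
#'
#' Holds the cross-validated accuracy observed on the true labels, the null
#' accuracies obtained under label permutation, and the add-one permutation
#' p-value \eqn{p = (1 + \#\{null \ge observed\}) / (B + 1)}. The smallest
#' attainable p with \eqn{B} permutations is \eqn{1/(B+1)}; the estimator
#' never returns 0.
#'
#' @slot observed numeric observed cross-validated accuracy in [0,1].
#' @slot nulls numeric vector of null accuracies (length = number of
#'   permutations).
#' @slot pValue numeric permutation p-value in (0,1].
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", nulls = "numeric", pValue = "numeric"))

setValidity("PermutationResult", function(object) {
  if (length(object@observed) != 1L || object@observed < 0 ||
      object@observed > 1)
    return("observed must be a single accuracy in [0,1]")
  if (length(object@nulls) < 1L) return("at least one null accuracy required")
  b <- length(object@nulls)
  expected <- (1 + sum(object@nulls >= object@observed)) / (b + 1)
  if (abs(object@pValue - expected) > 1e-12)
    return("pValue inconsistent with observed/nulls under the add-one rule")
  TRUE
})

#' @param observed observed cross-validated accuracy.
#' @param nulls vector of null (label-permuted) accuracies.
#' @rdname PermutationResult-class
#' @export
PermutationResult <- function(observed, nulls) {
  nulls <- as.numeric(nulls)
  p <- (1 + sum(nulls >= observed)) / (length(nulls) + 1)
  methods::new("PermutationResult", observed = as.numeric(observed),
               nulls = nulls, pValue = p)
}

#' Triple sex/age-matched reference assignment
#'
#' @slot assignments data.frame with columns \code{patient_id},
#'   \code{ref_id}, \code{age_diff} (integer years), three rows per patient.
#' @slot quality mean absolute age difference across all assignments.
#' @export
setClass("MatchedReference",
  representation(assignments = "data.frame", quality = "numeric"))

setValidity("MatchedReference", function(object) {
  a <- object@assignments
  miss <- setdiff(c("patient_id", "ref_id", "age_diff"), colnames(a))
  if (length(miss))
    return(paste0("missing assignment column(s): ",
                  paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a$ref_id))
      return("a reference individual is assigned to more than one patient")
    if (any(table(a$patient_id) != 3L))
      return("every patient must receive exactly 3 references")
  }
  TRUE
})

#' Cohort simulation settings
#'
#' Defines the synthetic study layout: cohort sizes (17 MRD-positive and 18
#' MRD-negative patients by default, with a 3x sex/age-matched reference
#' pool), the planted region-level event clusters with their per-group
#' carrier frequencies, and the background aberration process.
#'
#' @slot nMrdPos,nMrdNeg patient counts per MRD group.
#' @slot referenceMultiplier reference pool size as a multiple of the
#'   patient cohort (default 3).
#' @slot plantedClusters data.frame with columns \code{label}, \code{chrom},
#'   \code{start}, \code{end}, \code{event_type}, \code{freq_mrd_pos},
#'   \code{freq_mrd_neg}, \code{freq_reference}; see
#'   \code{\link{plantedClusterPresets}}.
#' @slot backgroundRate expected background segments per sample (Poisson).
#' @slot backgroundGenes number of background genes tiled genome-wide.
#' @slot genesPerCluster genes tiled inside each planted region.
#' @slot ageRange integer length-2 age range (years).
#' @slot probMale probability that a patient is male.
#' @slot mosaicRange length-2 range for mosaic fractions of planted losses.
#' @slot focalLosses if \code{FALSE} (default) planted losses span the whole
#'   chromosome arm containing the region, emulating broad subclonal
#'   chromosome losses; if \code{TRUE} they are focal to the region.
#' @slot markerDensity SNP markers per kb used to size marker counts.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  representation(nMrdPos = "integer", nMrdNeg = "integer",
                 referenceMultiplier = "integer",
                 plantedClusters = "data.frame",
                 backgroundRate = "numeric", backgroundGenes = "integer",
                 genesPerCluster = "integer", ageRange = "integer",
                 probMale = "numeric", mosaicRange = "numeric",
                 focalLosses = "logical", markerDensity = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nMrdPos + object@nMrdNeg <= 0L)
    return("need at least one patient")
  if (object@referenceMultiplier < 1L)
    return("referenceMultiplier must be >= 1")
  pc <- object@plantedClusters
  need <- c("label", "chrom", "start", "end", "event_type",
            "freq_mrd_pos", "freq_mrd_neg", "freq_reference")
  miss <- setdiff(need, colnames(pc))
  if (length(miss))
    return(paste0("plantedClusters missing column(s): ",
                  paste(miss, collapse = ", ")))
  fr <- unlist(pc[c("freq_mrd_pos", "freq_mrd_neg", "freq_reference")])
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    return("planted cluster frequencies must lie in [0, 1]")
  if (nrow(pc) > 1L) {
    gr <- GenomicRanges::GRanges(pc$chrom, IRanges::IRanges(pc$start, pc$end))
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
      return("planted cluster regions must not overlap")
  }
  if (nrow(pc) && !all(pc$event_type %in% EVENT_TYPES))
    return("planted cluster event_type outside vocabulary")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0L)
    return("ageRange must be an increasing length-2 integer vector")
  if (object@probMale < 0 || object@probMale > 1)
    return("probMale must lie in [0, 1]")
  if (object@backgroundRate < 0) return("backgroundRate must be >= 0")
  TRUE
})
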