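#' Canonicalise event types for feature encoding
#'
#' Mosaic losses are merged with losses (\code{loss_mosaic -> loss});
#' \code{gain} and \code{cnLOH} are unchanged. Encoding therefore never
#' distinguishes a clonal from a subclonal deletion of a gene.
#'
#' @param event_type character vector with values in the segment vocabulary.
#' @return character vector with values in \code{gain}, \code{loss},
#'   \code{cnLOH}.
#' @export
canonicalEvent <- function(event_type) {
  bad <- setdiff(unique(event_type), EVENT_TYPES)
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  ifelse(event_type == "loss_mosaic", "loss", event_type)
}

#' Pairwise 1-based inclusive interval overlap
#'
#' Two intervals overlap iff they lie on the same chromosome and share at
#' least one base: \code{max(starts) <= min(ends)}. Adjacent intervals
#' (\code{[100,200]} vs \code{[201,300]}) do not overlap. The relation is
#' symmetric. \code{a} and \code{b} are compared element-wise (recycled).
#'
#' @param a,b \code{GRanges} (or subclasses) of equal length (or length 1).
#' @return logical vector.
#' @export
intervalsOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) <=
    pmin(GenomicRanges::end(a), GenomicRanges::end(b))
}

#' Encode segments into the binary gene-by-event feature matrix
#'
#' A sample's entry for feature \code{"G:e"} is 1 iff at least one of its
#' QC-passed segments with canonical event \code{e} overlaps gene \code{G}
#' by at least one base (no minimum overlap fraction; mosaic fraction does
#' not weight the entry). Only (gene, event) pairs observed in at least one
#' sample become features; features are ordered lexicographically by id and
#' samples exactly as given, so the result is invariant to segment and
#' catalog order and to duplicated segments.
#'
#' @param calls an \linkS4class{AberrationCalls} object (QC-passed).
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param samples character vector fixing the sample order; every segment's
#'   \code{sample_id} must appear here. Samples without any overlapping
#'   segment get an all-zero column.
#' @param colData optional data.frame of per-sample annotation (e.g. the
#'   samples table); matched to \code{samples} by its \code{sample_id}
#'   column.
#' @return A \linkS4class{GeneEventMatrix} (features x samples).
#' @export
encodeGeneEvents <- function(calls, catalog, samples, colData = NULL) {
  stopifnot(is(calls, "AberrationCalls"), is(catalog, "GeneCatalog"))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  mc <- S4Vectors::mcols(calls)
  unknown <- setdiff(unique(mc$sample_id), samples)
  if (length(unknown))
    stop("segment(s) reference unknown sample(s): ",
         paste(unknown, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(calls, catalog, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  sym <- S4Vectors::mcols(catalog)$symbol[sh]
  ev <- canonicalEvent(mc$event_type[qh])
  fid <- paste0(sym, ":", ev)
  sid <- mc$sample_id[qh]
  feats <- lexSort(unique(fid))
  mat <- matrix(0L, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
  if (length(fid))
    mat[cbind(match(fid, feats), match(sid, samples))] <- 1L
  fsym <- sub(":(gain|loss|cnLOH)$", "", feats)
  fev <- sub("^.*:", "", feats)
  rd <- S4Vectors::DataFrame(
    symbol = fsym, event = fev,
    band = S4Vectors::mcols(catalog)$band[match(fsym,
                                        S4Vectors::mcols(catalog)$symbol)])
  cd <- S4Vectors::DataFrame(sample_id = samples, row.names = samples)
  if (!is.null(colData)) {
    m <- match(samples, colData$sample_id)
    if (anyNA(m)) stop("colData lacks sample(s): ",
                       paste(samples[is.na(m)], collapse = ", "))
    cd <- S4Vectors::DataFrame(colData[m, , drop = FALSE],
                               row.names = samples)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = mat), rowData = rd, colData = cd)
  methods::new("GeneEventMatrix", se)
}

#' MRD labels of a GeneEventMatrix
#'
#' Extracts \code{mrd_status} from the object's column annotation.
#'
#' @param gem a \linkS4class{GeneEventMatrix} whose \code{colData} carries
#'   \code{mrd_status}.
#' @return character vector aligned with \code{sampleIds(gem)}.
#' @export
mrdLabels <- function(gem) {
  cd <- SummarizedExperiment::colData(gem)
  if (!"mrd_status" %in% colnames(cd))
    stop("colData lacks an mrd_status column; pass labels explicitly")
  as.character(cd$mrd_status)
}
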