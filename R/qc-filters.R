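#' Segment validity (QC) filter
#'
#' Applies the per-event-class validity rules to CMA calls: cnLOH segments
#' are retained iff supported by at least \code{minMarkersLoh} SNP markers
#' (default 50); gains iff supported by at least \code{minMarkersGain}
#' markers (default 50) \emph{and} \code{mean_log2ratio >
#' minAbsLog2Ratio} (default 0.25); losses and mosaic losses iff supported
#' by at least \code{minMarkersLoss} markers (default 20) \emph{and}
#' \code{mean_log2ratio < -minAbsLog2Ratio}. Marker thresholds are
#' inclusive; the log2-ratio bound is strict. cnLOH is copy-neutral and has
#' no log2-ratio criterion. The filter is a pure selection: retained
#' segments are unaltered and input order is preserved, so it is idempotent.
#'
#' @param calls an \linkS4class{AberrationCalls} object.
#' @param thresholds a \linkS4class{QCThresholds} object.
#' @return The retained \linkS4class{AberrationCalls}.
#' @examples
#' calls <- AberrationCalls(
#'   sample_id = c("P01", "P01"), chrom = "chr19",
#'   start = c(1e6, 5e6), end = c(3e6, 9e6),
#'   event_type = c("cnLOH", "loss"), marker_count = c(49L, 20L),
#'   mean_log2ratio = c(NA, -0.3))
#' qcFilter(calls)  # drops the 49-marker cnLOH, keeps the loss
#' @export
qcFilter <- function(calls, thresholds = QCThresholds()) {
  stopifnot(is(calls, "AberrationCalls"), is(thresholds, "QCThresholds"))
  if (length(calls) == 0L) return(calls)
  mc <- S4Vectors::mcols(calls)
  cnv <- mc$event_type %in% c("gain", "loss", "loss_mosaic")
  if (any(cnv & is.na(mc$mean_log2ratio))) {
    bad <- which(cnv & is.na(mc$mean_log2ratio))[1]
    stop(sprintf("segment %d (%s, %s) lacks mean_log2ratio required for QC",
                 bad, mc$sample_id[bad], mc$event_type[bad]))
  }
  keep <- rep(FALSE, length(calls))
  loh <- mc$event_type == "cnLOH"
  keep[loh] <- mc$marker_count[loh] >= thresholds@minMarkersLoh
  g <- mc$event_type == "gain"
  keep[g] <- mc$marker_count[g] >= thresholds@minMarkersGain &
    mc$mean_log2ratio[g] > thresholds@minAbsLog2Ratio
  l <- mc$event_type %in% c("loss", "loss_mosaic")
  keep[l] <- mc$marker_count[l] >= thresholds@minMarkersLoss &
    mc$mean_log2ratio[l] < -thresholds@minAbsLog2Ratio
  calls[keep]
}

#' Landscape size filter
#'
#' Retains segments large enough for genome-wide landscape reporting:
#' gains/losses with size strictly exceeding \code{minCnvKbLandscape}
#' (default 500 kb) and cnLOH strictly exceeding \code{minLohKbLandscape}
#' (default 5000 kb). Used only for landscape figures/summaries — feature
#' encoding consumes all QC-passed segments regardless of size.
#'
#' @inheritParams qcFilter
#' @return The retained \linkS4class{AberrationCalls}, order preserved.
#' @export
landscapeFilter <- function(calls, thresholds = QCThresholds()) {
  stopifnot(is(calls, "AberrationCalls"), is(thresholds, "QCThresholds"))
  if (length(calls) == 0L) return(calls)
  kb <- segmentSizeKb(calls)
  loh <- S4Vectors::mcols(calls)$event_type == "cnLOH"
  keep <- ifelse(loh, kb > thresholds@minLohKbLandscape,
                 kb > thresholds@minCnvKbLandscape)
  calls[keep]
}
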