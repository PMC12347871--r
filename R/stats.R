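## Univariate per-feature contingency statistics, multiple-testing
## correction, group frequency tables, co-localized cluster detection and
## region summaries.

#' Per-feature 2x2 contingency counts
#'
#' Counts carriers and non-carriers of a feature per MRD group:
#' \code{a} = MRD-positive carriers, \code{b} = MRD-positive non-carriers,
#' \code{c} = MRD-negative carriers, \code{d} = MRD-negative non-carriers.
#'
#' @param gem a \linkS4class{GeneEventMatrix}.
#' @param labels two-class outcome aligned with \code{sampleIds(gem)}.
#' @param feature a feature id present in \code{gem}.
#' @param positiveClass label value treated as MRD-positive.
#' @return named integer vector \code{c(a, b, c, d)}.
#' @export
featureContingency <- function(gem, labels, feature,
                               positiveClass = "positive") {
  stopifnot(is(gem, "GeneEventMatrix"))
  if (!feature %in% rownames(gem))
    stop("unknown feature: ", feature)
  labels <- .checkLabels(labels, ncol(gem))
  v <- presenceMatrix(gem)[feature, ]
  pos <- labels == positiveClass
  c(a = sum(v[pos] == 1L), b = sum(v[pos] == 0L),
    c = sum(v[!pos] == 1L), d = sum(v[!pos] == 0L))
}

#' Two-sided Fisher exact p-value
#'
#' Exact two-sided p for a 2x2 table by the point-probability method: with
#' margins fixed, all hypergeometric tables whose point probability does
#' not exceed that of the observed table (up to a relative tolerance of
#' 1e-7 for floating-point ties, the usual exact-test convention) are
#' summed. Degenerate margins give p = 1. Vectorised over the four cell
#' arguments.
#'
#' @param a,b,c,d non-negative integer cell counts (\code{a,b} = first
#'   group carriers/non-carriers; \code{c,d} = second group).
#' @return p-value(s) in (0, 1].
#' @export
fisherExact <- function(a, b, c, d) {
  cells <- cbind(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells != floor(cells))) stop("cell counts must be integers")
  one <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    supp <- max(0L, k - r2):min(r1, k)
    pr <- stats::dhyper(supp, r1, r2, k)
    pobs <- stats::dhyper(a, r1, r2, k)
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  }
  unname(mapply(one, cells[, 1], cells[, 2], cells[, 3], cells[, 4]))
}

#' Sample odds ratio with Haldane-Anscombe correction
#'
#' \eqn{(a d)/(b c)}; when any cell is zero, 0.5 is added to all four cells
#' first, so the ratio is always finite and positive. This is the sample
#' (cross-product) odds ratio, not the conditional-MLE estimate reported by
#' \code{\link[stats]{fisher.test}}. Vectorised.
#'
#' @inheritParams fisherExact
#' @return odds ratio(s), non-negative and finite.
#' @export
oddsRatio <- function(a, b, c, d) {
  cells <- cbind(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  zero <- rowSums(cells == 0) > 0
  cells[zero, ] <- cells[zero, , drop = FALSE] + 0.5
  unname((cells[, 1] * cells[, 4]) / (cells[, 2] * cells[, 3]))
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up by default; Holm and Bonferroni available.
#' Adjusted values map back to the input positions and satisfy
#' \code{q >= p} and \code{q <= 1}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default), \code{"holm"} or
#'   \code{"bonferroni"}.
#' @return adjusted p-values in input order.
#' @export
adjustPvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Per-group carrier frequencies
#'
#' Carrier fraction of each feature in the MRD-positive group, the
#' MRD-negative group, and (when a reference matrix is supplied) the
#' reference cohort. Features absent from the reference matrix have
#' reference frequency 0.
#'
#' @inheritParams featureContingency
#' @param refGem optional \linkS4class{GeneEventMatrix} of the reference
#'   cohort.
#' @param features feature ids to report (default: all features of
#'   \code{gem}).
#' @return data.frame with columns \code{feature_id}, \code{freq_mrd_pos},
#'   \code{freq_mrd_neg} and, if \code{refGem} is given,
#'   \code{freq_reference}.
#' @export
groupFrequencies <- function(gem, labels, refGem = NULL, features = NULL,
                             positiveClass = "positive") {
  stopifnot(is(gem, "GeneEventMatrix"))
  labels <- .checkLabels(labels, ncol(gem))
  if (is.null(features)) features <- rownames(gem)
  miss <- setdiff(features, rownames(gem))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  m <- presenceMatrix(gem)[features, , drop = FALSE]
  pos <- labels == positiveClass
  if (!any(pos) || all(pos)) stop("both MRD groups must be non-empty")
  out <- data.frame(feature_id = features,
                    freq_mrd_pos = rowMeans(m[, pos, drop = FALSE]),
                    freq_mrd_neg = rowMeans(m[, !pos, drop = FALSE]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(refGem)) {
    stopifnot(is(refGem, "GeneEventMatrix"))
    if (ncol(refGem) == 0L) stop("reference cohort is empty")
    rm <- presenceMatrix(refGem)
    out$freq_reference <- ifelse(features %in% rownames(rm),
                                 rowMeans(rm[match(features, rownames(rm)),
                                             , drop = FALSE]), 0)
    out$freq_reference[is.na(out$freq_reference)] <- 0
  }
  out
}

#' Univariate feature statistics table
#'
#' For each requested feature: the 2x2 contingency counts against MRD
#' status, the two-sided Fisher exact p, the Haldane-Anscombe-corrected
#' odds ratio, the multiplicity-adjusted q-value, and per-group carrier
#' frequencies (including the reference cohort when supplied). Adjustment
#' is performed across exactly the requested feature set.
#'
#' @inheritParams groupFrequencies
#' @param method multiple-testing method, see \code{\link{adjustPvalues}}.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{band}, \code{event}, \code{a}, \code{b}, \code{c}, \code{d},
#'   frequency columns, \code{odds_ratio}, \code{p_raw}, \code{q_adj}.
#' @export
featureStats <- function(gem, labels, refGem = NULL, features = NULL,
                         method = "BH", positiveClass = "positive") {
  freqs <- groupFrequencies(gem, labels, refGem, features, positiveClass)
  features <- freqs$feature_id
  labels <- .checkLabels(labels, ncol(gem))
  m <- presenceMatrix(gem)[features, , drop = FALSE]
  pos <- labels == positiveClass
  a <- rowSums(m[, pos, drop = FALSE] == 1L)
  b <- rowSums(m[, pos, drop = FALSE] == 0L)
  cc <- rowSums(m[, !pos, drop = FALSE] == 1L)
  d <- rowSums(m[, !pos, drop = FALSE] == 0L)
  p <- fisherExact(a, b, cc, d)
  rd <- SummarizedExperiment::rowData(gem)[features, , drop = FALSE]
  out <- data.frame(
    feature_id = features,
    band = if ("band" %in% colnames(rd)) rd$band else NA_character_,
    event = rd$event,
    a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
    freqs[-1],
    odds_ratio = oddsRatio(a, b, cc, d),
    p_raw = p,
    q_adj = adjustPvalues(p, method),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_raw, out$feature_id, method = "radix"), ]
}

#' Detect co-localized aberration clusters among top features
#'
#' Groups top-ranked features that share a canonical event type and whose
#' genes form a genomically contiguous chain on one chromosome: adjacent
#' member genes may be separated by at most \code{maxGap} bases (default
#' 1 Mb, measured between gene ends), and a chain must contain at least
#' \code{minGenes} genes (default 5). Each cluster is labelled by its
#' spanned cytobands. The result is invariant to the input feature order.
#'
#' @param features character vector of feature ids (\code{"SYMBOL:event"}),
#'   or the data.frame returned by \code{\link{rankFeatures}}.
#' @param catalog a \linkS4class{GeneCatalog}; every feature's gene must be
#'   present.
#' @param gem,labels,refGem optional; when given, per-group carrier
#'   frequencies (mean over member genes) are attached to each cluster.
#' @param maxGap maximum inter-gene gap in bases.
#' @param minGenes minimum number of member genes.
#' @param positiveClass label value treated as MRD-positive.
#' @return data.frame with one row per cluster: \code{label}, \code{chrom},
#'   \code{start}, \code{end}, \code{event}, \code{n_genes},
#'   \code{genes}, \code{features} (comma-separated, in genomic order) and
#'   frequency columns when computable. Zero rows if no cluster qualifies.
#' @export
detectClusters <- function(features, catalog, gem = NULL, labels = NULL,
                           refGem = NULL, maxGap = 1e6, minGenes = 5L,
                           positiveClass = "positive") {
  stopifnot(is(catalog, "GeneCatalog"))
  if (is.data.frame(features)) features <- features$feature_id
  features <- unique(as.character(features))
  sym <- sub(":(gain|loss|cnLOH)$", "", features)
  ev <- sub("^.*:", "", features)
  if (!all(ev %in% c("gain", "loss", "cnLOH")))
    stop("feature ids must end in :gain, :loss or :cnLOH")
  csym <- S4Vectors::mcols(catalog)$symbol
  m <- match(sym, csym)
  if (anyNA(m))
    stop("feature gene(s) missing from catalog: ",
         paste(unique(sym[is.na(m)]), collapse = ", "))
  df <- data.frame(
    feature_id = features, symbol = sym, event = ev,
    chrom = as.character(GenomicRanges::seqnames(catalog))[m],
    start = GenomicRanges::start(catalog)[m],
    end = GenomicRanges::end(catalog)[m],
    band = S4Vectors::mcols(catalog)$band[m], stringsAsFactors = FALSE)
  df <- df[order(df$event, df$chrom, df$start, df$feature_id,
                 method = "radix"), ]
  ## chain genes within (event, chrom) runs; break where gap > maxGap
  newgrp <- !(duplicated(paste(df$event, df$chrom)) &
                c(FALSE, df$start[-1] - df$end[-nrow(df)] - 1 <= maxGap))
  if (nrow(df)) newgrp[1] <- TRUE
  grp <- cumsum(newgrp)
  out <- do.call(rbind, lapply(split(df, grp), function(g) {
    if (nrow(g) < minGenes) return(NULL)
    bands <- unique(g$band)
    data.frame(
      label = if (length(bands) > 1L)
        paste0(bands[1], "-", bands[length(bands)]) else bands,
      chrom = g$chrom[1], start = min(g$start), end = max(g$end),
      event = g$event[1], n_genes = nrow(g),
      genes = paste(g$symbol, collapse = ","),
      features = paste(g$feature_id, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      event = character(), n_genes = integer(),
                      genes = character(), features = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(gem) && !is.null(labels) && nrow(out)) {
    fr <- lapply(strsplit(out$features, ","), function(fs) {
      fs <- intersect(fs, rownames(gem))
      f <- groupFrequencies(gem, labels, refGem, fs, positiveClass)
      colMeans(f[, -1, drop = FALSE])
    })
    fr <- do.call(rbind, fr)
    out <- cbind(out, as.data.frame(fr))
  }
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}

#' Region summary statistics
#'
#' For each sample group, summarises the segments of a given canonical
#' event type that overlap a region: minimum, median and maximum of the
#' segment size (kb), of the SNP marker count, and of the number of catalog
#' genes each segment overlaps.
#'
#' @param calls an \linkS4class{AberrationCalls} object.
#' @param region a length-1 \code{GRanges} (or \code{"chr:start-end"}
#'   string).
#' @param event canonical event type (\code{gain}, \code{loss},
#'   \code{cnLOH}).
#' @param catalog a \linkS4class{GeneCatalog} used for gene counting.
#' @param groups named list of sample-id character vectors, one entry per
#'   group.
#' @return data.frame with columns \code{group}, \code{statistic}
#'   (\code{size_kb}, \code{marker_count}, \code{gene_count}), \code{min},
#'   \code{median}, \code{max}.
#' @export
regionSummary <- function(calls, region, event, catalog, groups) {
  stopifnot(is(calls, "AberrationCalls"), is(catalog, "GeneCatalog"),
            is.list(groups), !is.null(names(groups)))
  if (is.character(region)) region <- GenomicRanges::GRanges(region)
  if (length(region) != 1L) stop("region must be a single interval")
  mc <- S4Vectors::mcols(calls)
  inRegion <- canonicalEvent(mc$event_type) == event &
    GenomicRanges::countOverlaps(calls, region, ignore.strand = TRUE) > 0L
  out <- lapply(names(groups), function(gname) {
    sel <- inRegion & mc$sample_id %in% groups[[gname]]
    if (!any(sel))
      stop("no qualifying ", event, " segment overlapping the region in ",
           "group '", gname, "'")
    seg <- calls[sel]
    vals <- list(size_kb = segmentSizeKb(seg),
                 marker_count = S4Vectors::mcols(seg)$marker_count,
                 gene_count = GenomicRanges::countOverlaps(
                   seg, catalog, ignore.strand = TRUE))
    data.frame(group = gname, statistic = names(vals),
               min = vapply(vals, min, numeric(1)),
               median = vapply(vals, function(v) as.numeric(median(v)),
                               numeric(1)),
               max = vapply(vals, max, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Presence/absence heatmap matrix
#'
#' Returns the binary matrix underlying the top-feature heatmap: samples
#' ordered MRD-positive first, features ordered by rank.
#'
#' @param gem a \linkS4class{GeneEventMatrix}.
#' @param ranked data.frame from \code{\link{rankFeatures}} (or a feature
#'   id vector, taken in order).
#' @param labels two-class outcome aligned with \code{sampleIds(gem)}.
#' @param positiveClass label value treated as MRD-positive.
#' @return integer matrix, features x samples.
#' @export
heatmapMatrix <- function(gem, ranked, labels, positiveClass = "positive") {
  stopifnot(is(gem, "GeneEventMatrix"))
  if (is.data.frame(ranked)) ranked <- ranked$feature_id
  labels <- .checkLabels(labels, ncol(gem))
  miss <- setdiff(ranked, rownames(gem))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  ord <- c(which(labels == positiveClass), which(labels != positiveClass))
  presenceMatrix(gem)[ranked, ord, drop = FALSE]
}
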