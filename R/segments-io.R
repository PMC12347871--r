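## Readers/writers for the segment TSV, gene-catalog BED and samples TSV
## dialects. The segment and samples tables are header-required TSV with "."
## for absent values; the catalog is 5-column BED-like (chrom, start, end,
## symbol, band) with standard BED 0-based half-open coordinates on disk,
## converted to 1-based inclusive at this boundary. The band column sits
## where BED puts score/strand, so these files are parsed directly rather
## than through a BED importer.

SEGMENT_COLUMNS <- c("sample_id", "chrom", "start", "end", "event_type",
                     "marker_count", "mean_log2ratio", "mosaic_fraction")
SAMPLE_COLUMNS <- c("sample_id", "sex", "age", "mrd_status", "cohort")

#' Normalise event-type strings into the fixed vocabulary
#'
#' Case- and punctuation-insensitive: \code{"LOSS MOSAIC"},
#' \code{"Loss-Mosaic"} and \code{"loss_mosaic"} all map to
#' \code{loss_mosaic}; \code{"CN-LOH"}, \code{"cnLoh"} map to \code{cnLOH}.
#'
#' @param x character vector of event-type strings.
#' @return character vector with values in \code{gain}, \code{loss},
#'   \code{loss_mosaic}, \code{cnLOH}.
#' @export
parseEventType <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_|_$", "", key)
  map <- c(gain = "gain", loss = "loss", loss_mosaic = "loss_mosaic",
           cnloh = "cnLOH", cn_loh = "cnLOH")
  out <- unname(map[key])
  if (anyNA(out) && length(x)) {
    bad <- unique(x[is.na(out)])
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  }
  out
}

.numOrDot <- function(x, what, lines) {
  x[x == "."] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop(sprintf("line %d: non-numeric %s value '%s'",
                 lines[which(bad)[1]], what, x[which(bad)[1]]))
  out
}

#' Read a segment-call table
#'
#' Parses the tab-separated segment dialect (header required; columns
#' \code{sample_id chrom start end event_type marker_count mean_log2ratio
#' mosaic_fraction}; \code{"."} marks absent values). Coordinates are
#' 1-based inclusive. Unknown event-type strings, non-numeric coordinates
#' and negative marker counts are rejected with the offending line number.
#'
#' @param path path to the TSV file.
#' @return An \linkS4class{AberrationCalls} object, one segment per row.
#' @seealso \code{\link{writeSegments}}
#' @export
readSegments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "")
  miss <- setdiff(SEGMENT_COLUMNS, colnames(raw))
  if (length(miss))
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) return(AberrationCalls())
  lines <- seq_len(n) + 1L          # header occupies line 1
  start <- .numOrDot(raw$start, "start coordinate", lines)
  end <- .numOrDot(raw$end, "end coordinate", lines)
  if (anyNA(start) || anyNA(end))
    stop(sprintf("line %d: missing coordinate",
                 lines[which(is.na(start) | is.na(end))[1]]))
  mk <- .numOrDot(raw$marker_count, "marker_count", lines)
  if (anyNA(mk) || any(mk < 0) || any(mk != floor(mk)))
    stop(sprintf("line %d: marker_count must be a non-negative integer",
                 lines[which(is.na(mk) | mk < 0 | mk != floor(mk))[1]]))
  bad <- start < 1 | end < start
  if (any(bad))
    stop(sprintf("line %d: invalid interval [%s, %s]",
                 lines[which(bad)[1]], raw$start[which(bad)[1]],
                 raw$end[which(bad)[1]]))
  AberrationCalls(
    sample_id = raw$sample_id, chrom = raw$chrom,
    start = start, end = end, event_type = raw$event_type,
    marker_count = as.integer(mk),
    mean_log2ratio = .numOrDot(raw$mean_log2ratio, "mean_log2ratio", lines),
    mosaic_fraction = .numOrDot(raw$mosaic_fraction, "mosaic_fraction",
                                lines))
}

.fmtNum <- function(x) ifelse(is.na(x), ".", sprintf("%.15g", x))

#' Write a segment-call table
#'
#' Inverse of \code{\link{readSegments}}; numeric fields are written with 15
#' significant digits, \code{NA} as \code{"."}.
#'
#' @param calls an \linkS4class{AberrationCalls} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegments <- function(calls, path) {
  stopifnot(is(calls, "AberrationCalls"))
  mc <- S4Vectors::mcols(calls)
  df <- data.frame(
    sample_id = mc$sample_id,
    chrom = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls),
    end = GenomicRanges::end(calls),
    event_type = mc$event_type,
    marker_count = mc$marker_count,
    mean_log2ratio = .fmtNum(mc$mean_log2ratio),
    mosaic_fraction = .fmtNum(mc$mosaic_fraction),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene catalog from a BED-like file
#'
#' Expects five tab-separated columns without header: chromosome, start,
#' end, gene symbol, cytoband. On-disk coordinates follow BED semantics
#' (0-based half-open) and are converted to the package's 1-based inclusive
#' convention (\code{[start+1, end]}). Duplicate symbols and empty intervals
#' are rejected.
#'
#' @param path path to the catalog file.
#' @return A \linkS4class{GeneCatalog}.
#' @export
readGeneCatalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(GeneCatalog())
  raw <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 5L)
    stop("gene catalog must have 5 columns: chrom, start, end, symbol, band")
  colnames(raw)[1:5] <- c("chrom", "start", "end", "symbol", "band")
  start0 <- .numOrDot(raw$start, "start coordinate", seq_len(nrow(raw)))
  end0 <- .numOrDot(raw$end, "end coordinate", seq_len(nrow(raw)))
  bad <- is.na(start0) | is.na(end0) | end0 <= start0 | start0 < 0
  if (any(bad))
    stop(sprintf("row %d: invalid BED interval [%s, %s)", which(bad)[1],
                 raw$start[which(bad)[1]], raw$end[which(bad)[1]]))
  if (anyDuplicated(raw$symbol))
    stop("duplicate gene symbol(s) in catalog: ",
         paste(unique(raw$symbol[duplicated(raw$symbol)]), collapse = ", "))
  GeneCatalog(symbol = raw$symbol, chrom = raw$chrom,
              start = start0 + 1, end = end0, band = raw$band)
}

#' Write a gene catalog as a BED-like file
#'
#' Converts internal 1-based inclusive coordinates back to BED 0-based
#' half-open. No header is written.
#'
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "GeneCatalog"))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(catalog)),
    start = GenomicRanges::start(catalog) - 1L,
    end = GenomicRanges::end(catalog),
    symbol = S4Vectors::mcols(catalog)$symbol,
    band = S4Vectors::mcols(catalog)$band,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write sample/clinical tables
#'
#' Header-required TSV with columns \code{sample_id}, \code{sex} (M/F),
#' \code{age} (integer years), \code{mrd_status} (\code{positive},
#' \code{negative} or \code{unknown}) and \code{cohort} (\code{patient} or
#' \code{reference}). Reference records must have \code{mrd_status}
#' \code{unknown}.
#'
#' @param path path to the TSV file.
#' @return \code{readSamples}: a data.frame with the columns above.
#' @export
readSamples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "")
  miss <- setdiff(SAMPLE_COLUMNS, colnames(df))
  if (length(miss))
    stop("samples table is missing column(s): ", paste(miss, collapse = ", "))
  df$age <- as.integer(df$age)
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(df$mrd_status %in% c("positive", "negative", "unknown")))
    stop("mrd_status must be positive, negative or unknown")
  if (!all(df$cohort %in% c("patient", "reference")))
    stop("cohort must be patient or reference")
  if (any(df$cohort == "reference" & df$mrd_status != "unknown"))
    stop("reference records must have mrd_status 'unknown'")
  df[SAMPLE_COLUMNS]
}

#' @param samples data.frame as returned by \code{readSamples}.
#' @rdname readSamples
#' @export
writeSamples <- function(samples, path) {
  write.table(samples[SAMPLE_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
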