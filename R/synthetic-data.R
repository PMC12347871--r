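## Synthetic cohort generator. Emulates the study layout the analysis
## assumes: 35 labelled B-ALL patients (17 MRD-positive / 18 MRD-negative),
## a 3x sex/age-matched healthy reference pool, three planted region-level
## aberration clusters (a 19q13-like cnLOH cluster and two broad mosaic-loss
## regions on 7p and 16q) at configurable per-group carrier frequencies,
## plus a Poisson background of random aberrations. A single RNG stream per
## stage, derived from the master seed with fixed offsets
## (patients/segments = seed + 1, reference pool = seed + 2; the catalog is
## deterministic), keeps cohort labels stable when the background layout
## changes.

## approximate autosome lengths (bp) and centromere midpoints, GRCh38 scale
CHROM_SIZES <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468)

CENTROMERES <- c(
  chr1 = 123.4e6, chr2 = 93.9e6, chr3 = 90.9e6, chr4 = 50.0e6, chr5 = 48.8e6,
  chr6 = 59.8e6, chr7 = 60.1e6, chr8 = 45.2e6, chr9 = 43.0e6, chr10 = 39.8e6,
  chr11 = 53.4e6, chr12 = 35.5e6, chr13 = 17.7e6, chr14 = 17.2e6,
  chr15 = 19.0e6, chr16 = 36.8e6, chr17 = 25.1e6, chr18 = 18.5e6,
  chr19 = 26.2e6, chr20 = 28.1e6, chr21 = 12.0e6, chr22 = 15.0e6)

#' Planted-cluster presets
#'
#' Returns the default planted region clusters: a 19q13-like cnLOH region
#' and two mosaic-loss regions on 7p22 and 16q13. The \code{"abstract"}
#' preset plants the cnLOH cluster at carrier frequencies 0.70 (MRD+) /
#' 0.16 (MRD-) / 0.47 (reference); the \code{"table1"} preset uses the
#' per-group carrier counts 13/17 and 3/18 instead (13/17 = 0.765). Both
#' presets plant the loss regions at 6/17 and 1/18 with frequency 0 in the
#' reference pool. The two parameterisations differ slightly (0.70 vs
#' 13/17); they are exposed as alternatives rather than reconciled.
#'
#' @param preset \code{"abstract"} (default) or \code{"table1"}.
#' @return data.frame with columns \code{label}, \code{chrom}, \code{start},
#'   \code{end}, \code{event_type}, \code{freq_mrd_pos}, \code{freq_mrd_neg},
#'   \code{freq_reference}.
#' @export
plantedClusterPresets <- function(preset = c("abstract", "table1")) {
  preset <- match.arg(preset)
  loh_pos <- if (preset == "abstract") 0.70 else 13 / 17
  loh_neg <- if (preset == "abstract") 0.16 else 3 / 18
  data.frame(
    label = c("19q13.2-19q13.31", "7p22.3", "16q13"),
    chrom = c("chr19", "chr7", "chr16"),
    start = c(39000001, 100001, 55500001),
    end = c(40500000, 1600000, 57000000),
    event_type = c("cnLOH", "loss_mosaic", "loss_mosaic"),
    freq_mrd_pos = c(loh_pos, 6 / 17, 6 / 17),
    freq_mrd_neg = c(loh_neg, 1 / 18, 1 / 18),
    freq_reference = c(0.47, 0, 0),
    stringsAsFactors = FALSE)
}

#' @param nMrdPos,nMrdNeg,referenceMultiplier,plantedClusters,backgroundRate,backgroundGenes,genesPerCluster,ageRange,probMale,mosaicRange,focalLosses,markerDensity,seed
#'   see the slot documentation of \linkS4class{SimulationConfig}.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(nMrdPos = 17L, nMrdNeg = 18L,
                             referenceMultiplier = 3L,
                             plantedClusters = plantedClusterPresets(),
                             backgroundRate = 5, backgroundGenes = 300L,
                             genesPerCluster = 12L,
                             ageRange = c(18L, 58L), probMale = 0.55,
                             mosaicRange = c(0.2, 0.8),
                             focalLosses = FALSE, markerDensity = 0.13,
                             seed = 1L) {
  methods::new("SimulationConfig",
    nMrdPos = as.integer(nMrdPos), nMrdNeg = as.integer(nMrdNeg),
    referenceMultiplier = as.integer(referenceMultiplier),
    plantedClusters = plantedClusters,
    backgroundRate = as.numeric(backgroundRate),
    backgroundGenes = as.integer(backgroundGenes),
    genesPerCluster = as.integer(genesPerCluster),
    ageRange = as.integer(ageRange), probMale = as.numeric(probMale),
    mosaicRange = as.numeric(mosaicRange),
    focalLosses = as.logical(focalLosses),
    markerDensity = as.numeric(markerDensity), seed = as.integer(seed))
}

.clusterSymbolPrefix <- function(label) {
  toupper(gsub("[^A-Za-z0-9].*$", "", gsub("^([0-9]+)", "C\\1", label)))
}

#' Generate a synthetic gene catalog
#'
#' Tiles \code{genesPerCluster} genes (default 12) inside each planted
#' region — emulating dense gene clusters such as the PSG family on 19q13
#' or the metallothionein cluster on 16q13 — plus \code{backgroundGenes}
#' genes spaced evenly across the autosomes. Background genes are never
#' placed within 1 Mb of a planted region, so co-localised clusters among
#' top-ranked features can only arise from the planted regions or from a
#' genuinely recurrent background. For a region labelled with a band range
#' (e.g. \code{"19q13.2-19q13.31"}) the first half of its genes carry the
#' lower band and the rest the upper band. The catalog is fully
#' deterministic given the configuration.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GeneCatalog} sorted by genomic position.
#' @export
generateGeneCatalog <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  pc <- config@plantedClusters
  sym <- chrom <- band <- character(0)
  start <- end <- numeric(0)
  for (i in seq_len(nrow(pc))) {
    n <- config@genesPerCluster
    w <- pc$end[i] - pc$start[i] + 1
    pitch <- floor(w / n)
    glen <- max(1, floor(pitch / 2))
    s <- pc$start[i] + (seq_len(n) - 1L) * pitch
    bands <- strsplit(pc$label[i], "-", fixed = TRUE)[[1]]
    b <- if (length(bands) == 2L)
      ifelse(seq_len(n) <= n / 2, bands[1], bands[2]) else rep(pc$label[i], n)
    sym <- c(sym, sprintf("%sG%02d", .clusterSymbolPrefix(pc$label[i]),
                          seq_len(n)))
    chrom <- c(chrom, rep(pc$chrom[i], n))
    start <- c(start, s)
    end <- c(end, s + glen - 1)
    band <- c(band, b)
  }
  if (config@backgroundGenes > 0L) {
    total <- sum(CHROM_SIZES)
    pos <- (seq_len(config@backgroundGenes) - 0.5) *
      (total / config@backgroundGenes)
    cum <- cumsum(as.numeric(CHROM_SIZES))
    ci <- findInterval(pos, c(0, cum), rightmost.closed = TRUE)
    off <- floor(pos - c(0, cum)[ci]) + 1
    bchrom <- names(CHROM_SIZES)[ci]
    bstart <- pmin(off, CHROM_SIZES[ci] - 20000)
    bend <- bstart + 19999
    ## drop background genes near a planted region (1 Mb guard band)
    if (nrow(pc)) {
      guard <- GenomicRanges::GRanges(
        pc$chrom,
        IRanges::IRanges(pmax(1, pc$start - 1e6), pc$end + 1e6))
      bg <- GenomicRanges::GRanges(bchrom, IRanges::IRanges(bstart, bend))
      hit <- GenomicRanges::countOverlaps(bg, guard) > 0L
    } else hit <- rep(FALSE, length(bchrom))
    keep <- which(!hit)
    num <- sub("^chr", "", bchrom[keep])
    mid <- (bstart[keep] + bend[keep]) / 2
    arm <- ifelse(mid < CENTROMERES[paste0("chr", num)], "p", "q")
    sym <- c(sym, sprintf("BG%04d", keep))
    chrom <- c(chrom, bchrom[keep])
    start <- c(start, bstart[keep])
    end <- c(end, bend[keep])
    band <- c(band, sprintf("%s%s%d", num, arm, pmax(1, floor(mid / 1e7))))
  }
  cat <- GeneCatalog(symbol = sym, chrom = chrom, start = start, end = end,
                     band = band)
  GenomicRanges::sort(cat, ignore.strand = TRUE)
}

## segment builders -----------------------------------------------------

.plantedSegments <- function(cfg, ids, carrierMask, cluster, thresholds) {
  ## carrierMask: logical over ids; draws already consumed by caller
  idx <- which(carrierMask)
  n <- length(idx)
  if (n == 0L)
    return(NULL)
  if (cluster$event_type == "cnLOH" || cfg@focalLosses) {
    ## region-spanning segment with outward jitter (always covers all genes)
    s <- cluster$start - floor(runif(n, 0, 2e5))
    e <- cluster$end + floor(runif(n, 0, 2e5))
  } else {
    ## broad subclonal loss of the whole chromosome arm holding the region
    cen <- CENTROMERES[[cluster$chrom]]
    len <- CHROM_SIZES[[cluster$chrom]]
    if (cluster$end < cen) { s <- rep(1, n); e <- rep(floor(cen) - 1, n) }
    else { s <- rep(floor(cen), n); e <- rep(len, n) }
    runif(n)  # consume one draw per segment to keep the stream aligned
  }
  kb <- (e - s + 1) / 1000
  markers <- pmax(50L, as.integer(round(kb * cfg@markerDensity *
                                          runif(n, 0.9, 1.1))))
  isLoss <- cluster$event_type %in% c("loss", "loss_mosaic")
  lr <- if (isLoss) round(-runif(n, 0.3, 0.6), 4) else NA_real_
  mf <- if (cluster$event_type == "loss_mosaic")
    round(runif(n, cfg@mosaicRange[1], cfg@mosaicRange[2]), 4) else NA_real_
  data.frame(sample_id = ids[idx], chrom = cluster$chrom, start = s, end = e,
             event_type = cluster$event_type, marker_count = markers,
             mean_log2ratio = rep_len(lr, n),
             mosaic_fraction = rep_len(mf, n), stringsAsFactors = FALSE)
}

.backgroundSegments <- function(cfg, ids) {
  counts <- rpois(length(ids), cfg@backgroundRate)
  n <- sum(counts)
  if (n == 0L) return(NULL)
  who <- rep(ids, counts)
  ci <- sample(length(CHROM_SIZES), n, replace = TRUE,
               prob = as.numeric(CHROM_SIZES))
  chrom <- names(CHROM_SIZES)[ci]
  size <- floor(exp(runif(n, log(1e5), log(1e7))))   # 100 kb .. 10 Mb
  start <- floor(runif(n, 1, CHROM_SIZES[ci] - size)) + 1
  type <- EVENT_TYPES[sample.int(4L, n, replace = TRUE)]
  kb <- size / 1000
  floorMk <- ifelse(type %in% c("cnLOH", "gain"), 50L, 20L)
  markers <- pmax(floorMk,
                  as.integer(round(kb * cfg@markerDensity *
                                     runif(n, 0.9, 1.1))))
  lr <- rep(NA_real_, n)
  lr[type == "gain"] <- round(runif(sum(type == "gain"), 0.3, 0.6), 4)
  nl <- type %in% c("loss", "loss_mosaic")
  lr[nl] <- round(-runif(sum(nl), 0.3, 0.6), 4)
  mf <- rep(NA_real_, n)
  mf[type == "loss_mosaic"] <- round(runif(sum(type == "loss_mosaic"),
                                           cfg@mosaicRange[1],
                                           cfg@mosaicRange[2]), 4)
  data.frame(sample_id = who, chrom = chrom, start = start, end = start +
               size - 1, event_type = type, marker_count = markers,
             mean_log2ratio = lr, mosaic_fraction = mf,
             stringsAsFactors = FALSE)
}

.bindCalls <- function(parts) {
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) return(AberrationCalls())
  df <- do.call(rbind, parts)
  AberrationCalls(sample_id = df$sample_id, chrom = df$chrom,
                  start = df$start, end = df$end,
                  event_type = df$event_type,
                  marker_count = df$marker_count,
                  mean_log2ratio = df$mean_log2ratio,
                  mosaic_fraction = df$mosaic_fraction)
}

#' Generate the labelled patient cohort
#'
#' Draws patient demographics (sex Bernoulli with \code{probMale}, age
#' uniform-integer over \code{ageRange}) and segment calls: each sample
#' carries each planted cluster event independently with its MRD-group
#' frequency, and a Poisson(\code{backgroundRate}) number of background
#' segments with log-uniform sizes between 100 kb and 10 Mb. All emitted
#' segments pass \code{\link{qcFilter}} with default thresholds by
#' construction. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{patients} (data.frame: sample_id, sex,
#'   age, mrd_status, cohort) and \code{calls}
#'   (\linkS4class{AberrationCalls}).
#' @export
generateCohort <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed + 1L, {
    n <- config@nMrdPos + config@nMrdNeg
    ids <- sprintf("P%03d", seq_len(n))
    status <- rep(c("positive", "negative"),
                  c(config@nMrdPos, config@nMrdNeg))
    sex <- ifelse(runif(n) < config@probMale, "M", "F")
    age <- sample(seq(config@ageRange[1], config@ageRange[2]), n,
                  replace = TRUE)
    patients <- data.frame(sample_id = ids, sex = sex, age = age,
                           mrd_status = status, cohort = "patient",
                           stringsAsFactors = FALSE)
    pc <- config@plantedClusters
    freqs <- lapply(seq_len(nrow(pc)), function(i)
      ifelse(status == "positive", pc$freq_mrd_pos[i], pc$freq_mrd_neg[i]))
    calls <- local({
      parts <- list()
      for (i in seq_len(nrow(pc))) {
        carrier <- runif(n) < freqs[[i]]
        parts[[length(parts) + 1L]] <-
          .plantedSegments(config, ids, carrier, pc[i, ], NULL)
      }
      parts[[length(parts) + 1L]] <- .backgroundSegments(config, ids)
      .bindCalls(parts)
    })
    list(patients = patients, calls = calls)
  })
}

#' Generate the sex/age-matched reference pool
#'
#' Emits \code{referenceMultiplier} (default 3) reference individuals per
#' patient, copying each patient's sex and jittering the age by up to
#' \eqn{\pm 2} years (clamped to the configured range), so exact-sex
#' nearest-age triple matching is always feasible. Planted cluster events
#' are carried with \code{freq_reference}; background segments as in the
#' patient cohort. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param patients patient data.frame from \code{\link{generateCohort}}.
#' @return list with elements \code{references} (data.frame) and
#'   \code{calls} (\linkS4class{AberrationCalls}).
#' @export
generateReferencePool <- function(config, patients) {
  stopifnot(is(config, "SimulationConfig"), nrow(patients) > 0L)
  withSeed(config@seed + 2L, {
    m <- config@referenceMultiplier
    n <- nrow(patients) * m
    ids <- sprintf("R%03d", seq_len(n))
    sex <- rep(patients$sex, each = m)
    age <- pmin(pmax(rep(patients$age, each = m) +
                       sample(-2:2, n, replace = TRUE),
                     config@ageRange[1]), config@ageRange[2])
    refs <- data.frame(sample_id = ids, sex = sex, age = as.integer(age),
                       mrd_status = "unknown", cohort = "reference",
                       stringsAsFactors = FALSE)
    pc <- config@plantedClusters
    calls <- local({
      parts <- list()
      for (i in seq_len(nrow(pc))) {
        carrier <- runif(n) < pc$freq_reference[i]
        parts[[length(parts) + 1L]] <-
          .plantedSegments(config, ids, carrier, pc[i, ], NULL)
      }
      parts[[length(parts) + 1L]] <- .backgroundSegments(config, ids)
      .bindCalls(parts)
    })
    list(references = refs, calls = calls)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running, in a documented order, the catalog
#' (deterministic), the patient cohort (seed + 1) and the reference pool
#' (seed + 2), so each stage can also be regenerated in isolation.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{config}, \code{catalog},
#'   \code{patients}, \code{patientCalls}, \code{references},
#'   \code{referenceCalls}.
#' @export
simulateStudy <- function(config = SimulationConfig()) {
  catalog <- generateGeneCatalog(config)
  cohort <- generateCohort(config)
  pool <- generateReferencePool(config, cohort$patients)
  list(config = config, catalog = catalog, patients = cohort$patients,
       patientCalls = cohort$calls, references = pool$references,
       referenceCalls = pool$calls)
}

#' Write a simulated study to disk
#'
#' Writes \code{segments.tsv}, \code{reference_segments.tsv},
#' \code{catalog.bed} and \code{samples.tsv} (patients and references
#' combined) into \code{dir} using the package's interchange dialects.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    segments = file.path(dir, "segments.tsv"),
    reference_segments = file.path(dir, "reference_segments.tsv"),
    catalog = file.path(dir, "catalog.bed"),
    samples = file.path(dir, "samples.tsv"))
  writeSegments(sim$patientCalls, paths[["segments"]])
  writeSegments(sim$referenceCalls, paths[["reference_segments"]])
  writeGeneCatalog(sim$catalog, paths[["catalog"]])
  writeSamples(rbind(sim$patients, sim$references), paths[["samples"]])
  invisible(paths)
}
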