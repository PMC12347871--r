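## End-to-end driver: simulate (or read) -> QC -> encode -> rank/permtest ->
## univariate stats -> cluster detection -> reference matching/comparison,
## with every stage's interface file written to the output directory and a
## JSON run manifest tying the counts together.

.stageLog <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on either a simulated study
#' (\code{simConfig}) or on-disk inputs (\code{segmentsPath},
#' \code{catalogPath}, \code{samplesPath}, optional
#' \code{referenceSegmentsPath}); exactly one input mode must be supplied.
#' Stages: segment QC, gene-by-event encoding, random-forest feature
#' ranking, label-permutation significance test, univariate Fisher
#' statistics with multiple-testing correction, co-localized cluster
#' detection, and — when a reference cohort is present — triple sex/age
#' matching plus patient-vs-reference frequency comparison. All tabular
#' outputs are TSV with headers; the cluster report, permutation result and
#' run manifest are JSON. Runs are deterministic for a fixed seed.
#'
#' @param simConfig a \linkS4class{SimulationConfig}, or \code{NULL} when
#'   reading inputs from disk.
#' @param segmentsPath,catalogPath,samplesPath,referenceSegmentsPath input
#'   paths (ignored when \code{simConfig} is given).
#' @param outDir output directory, created if needed.
#' @param qc a \linkS4class{QCThresholds}.
#' @param model a \linkS4class{ModelConfig}; its seed is derived from
#'   \code{seed} unless the object is passed explicitly.
#' @param seed master seed; stage sub-seeds are derived from it (simulation
#'   uses \code{seed}, the classifier \code{seed + 100}).
#' @param adjustMethod multiple-testing method for the statistics table.
#' @param maxGap,minGenes cluster-detection settings, see
#'   \code{\link{detectClusters}}.
#' @param withReference set \code{FALSE} to skip matching and reference
#'   comparison even when a reference cohort is available; patient-side
#'   outputs are unaffected.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with all in-memory stage results plus
#'   \code{manifest}.
#' @export
runPipeline <- function(simConfig = NULL, segmentsPath = NULL,
                        catalogPath = NULL, samplesPath = NULL,
                        referenceSegmentsPath = NULL, outDir,
                        qc = QCThresholds(), model = NULL, seed = 1L,
                        adjustMethod = "BH", maxGap = 1e6, minGenes = 5L,
                        withReference = TRUE, quiet = FALSE) {
  fromFiles <- !is.null(segmentsPath) || !is.null(catalogPath) ||
    !is.null(samplesPath)
  if (is.null(simConfig) == !fromFiles)
    stop("supply exactly one of simConfig or input paths")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (is.null(model)) model <- ModelConfig(seed = as.integer(seed) + 100L)

  manifest <- list(package = "cmaMRD",
                   version = as.character(packageVersion("cmaMRD")),
                   seed = as.integer(seed),
                   stages = character(0), counts = list(), complete = FALSE)
  jsonOut <- function(x, f) jsonlite::write_json(
    x, file.path(outDir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsvOut <- function(df, f) write.table(
    df, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  ran <- function(stage) manifest$stages <<- c(manifest$stages, stage)

  ## --- input stage -----------------------------------------------------
  if (!is.null(simConfig)) {
    stopifnot(is(simConfig, "SimulationConfig"))
    simConfig@seed <- as.integer(seed)
    sim <- simulateStudy(simConfig)
    writeSimulation(sim, outDir)
    catalog <- sim$catalog
    samples <- rbind(sim$patients, sim$references)
    calls <- sim$patientCalls
    refCalls <- sim$referenceCalls
    .stageLog(quiet, "simulate", "%d patients, %d references, %d+%d segments",
              nrow(sim$patients), nrow(sim$references), length(calls),
              length(refCalls))
    ran("simulate")
  } else {
    if (is.null(segmentsPath) || is.null(catalogPath) ||
        is.null(samplesPath))
      stop("file input needs segmentsPath, catalogPath and samplesPath")
    allCalls <- readSegments(segmentsPath)
    catalog <- readGeneCatalog(catalogPath)
    samples <- readSamples(samplesPath)
    refCalls <- if (!is.null(referenceSegmentsPath))
      readSegments(referenceSegmentsPath) else NULL
    patIds <- samples$sample_id[samples$cohort == "patient"]
    calls <- allCalls[S4Vectors::mcols(allCalls)$sample_id %in% patIds]
    if (is.null(refCalls)) {
      refIds <- samples$sample_id[samples$cohort == "reference"]
      refCalls <- allCalls[S4Vectors::mcols(allCalls)$sample_id %in% refIds]
    }
    ran("read")
  }
  patients <- samples[samples$cohort == "patient", , drop = FALSE]
  references <- samples[samples$cohort == "reference", , drop = FALSE]
  haveRef <- withReference && nrow(references) > 0L
  manifest$counts$patients <- nrow(patients)
  manifest$counts$references <- nrow(references)
  manifest$counts$segments_in <- length(calls)

  ## --- QC --------------------------------------------------------------
  calls <- qcFilter(calls, qc)
  if (haveRef) refCalls <- qcFilter(refCalls, qc)
  manifest$counts$segments_qc <- length(calls)
  .stageLog(quiet, "qc", "%d patient segments retained", length(calls))
  ran("qc")

  ## --- encoding --------------------------------------------------------
  gem <- encodeGeneEvents(calls, catalog, patients$sample_id,
                          colData = patients)
  labels <- mrdLabels(gem)
  manifest$counts$features <- nrow(gem)
  manifest$counts$encoded_samples <- ncol(gem)
  stopifnot(ncol(gem) == nrow(patients))
  .stageLog(quiet, "encode", "%d features x %d samples", nrow(gem),
            ncol(gem))
  ran("encode")

  ## --- classifier ------------------------------------------------------
  ranked <- rankFeatures(gem, labels, model)
  tsvOut(ranked, "importance.tsv")
  perm <- permutationTest(gem, labels, model)
  jsonOut(list(observed_accuracy = observedAccuracy(perm),
               p_value = pValue(perm),
               n_permutations = length(nullAccuracies(perm)),
               null_accuracies = nullAccuracies(perm)),
          "permutation.json")
  manifest$counts$ranked_features <- nrow(ranked)
  .stageLog(quiet, "classifier", "observed accuracy %.3f, p = %.4g",
            observedAccuracy(perm), pValue(perm))
  ran("classifier")

  ## --- univariate statistics ------------------------------------------
  refGem <- NULL
  if (haveRef)
    refGem <- encodeGeneEvents(refCalls, catalog, references$sample_id,
                               colData = references)
  statsTab <- featureStats(gem, labels, refGem, ranked$feature_id,
                           method = adjustMethod)
  tsvOut(statsTab, "feature_stats.tsv")
  clusters <- detectClusters(ranked, catalog, gem, labels, refGem,
                             maxGap = maxGap, minGenes = minGenes)
  jsonOut(clusters, "clusters.json")
  tsvOut(heatmapMatrix(gem, ranked, labels), "heatmap_matrix.tsv")
  manifest$counts$clusters <- nrow(clusters)
  .stageLog(quiet, "stats", "%d features tested, %d cluster(s)",
            nrow(statsTab), nrow(clusters))
  ran("stats")

  ## --- reference matching/comparison ----------------------------------
  matching <- comparison <- NULL
  if (haveRef) {
    matching <- matchTriple(patients, references)
    tsvOut(assignments(matching), "matching.tsv")
    comparison <- compareWithReference(gem, refGem, ranked$feature_id)
    tsvOut(comparison, "reference_comparison.tsv")
    manifest$counts$matched_patients <-
      length(unique(assignments(matching)$patient_id))
    .stageLog(quiet, "match", "mean |age diff| %.2f years",
              matchQuality(matching))
    ran("match")
  }

  ## --- summary + manifest ----------------------------------------------
  summary <- list(
    observed_accuracy = observedAccuracy(perm),
    permutation_p = pValue(perm),
    n_features = nrow(gem),
    top_clusters = clusters)
  jsonOut(summary, "summary.json")
  manifest$complete <- TRUE
  jsonOut(manifest, "manifest.json")
  ran("report")
  invisible(list(manifest = manifest, gem = gem, labels = labels,
                 ranked = ranked, permutation = perm, stats = statsTab,
                 clusters = clusters, matching = matching,
                 comparison = comparison, refGem = refGem,
                 catalog = catalog, patients = patients,
                 references = references))
}
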