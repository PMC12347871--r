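## Synthetic-data generator: determinism, study layout, planted-event
## frequencies and QC-by-construction.

test_that("simulation is fully deterministic under a fixed seed", {
  a <- simulateStudy(SimulationConfig(seed = 11L))
  b <- simulateStudy(SimulationConfig(seed = 11L))
  expect_identical(a$patients, b$patients)
  expect_identical(a$references, b$references)
  expect_identical(grdf(a$patientCalls),
                   grdf(b$patientCalls))
  expect_identical(grdf(a$referenceCalls),
                   grdf(b$referenceCalls))
  expect_identical(grdf(a$catalog), grdf(b$catalog))
})

test_that("default layout matches the assumed study structure", {
  sim <- simulateStudy(SimulationConfig(seed = 2L))
  expect_equal(nrow(sim$patients), 35L)
  expect_equal(sum(sim$patients$mrd_status == "positive"), 17L)
  expect_equal(sum(sim$patients$mrd_status == "negative"), 18L)
  expect_equal(nrow(sim$references), 105L)
  expect_true(all(sim$references$mrd_status == "unknown"))
  expect_true(all(sim$patients$age >= 18 & sim$patients$age <= 58))
})

test_that("catalog tiles dense gene clusters inside each planted region", {
  cfg <- SimulationConfig(seed = 1L)
  cat <- generateGeneCatalog(cfg)
  pc <- cfg@plantedClusters
  for (i in seq_len(nrow(pc))) {
    region <- GenomicRanges::GRanges(pc$chrom[i],
                                     IRanges::IRanges(pc$start[i], pc$end[i]))
    inside <- GenomicRanges::countOverlaps(cat, region) > 0
    expect_gte(sum(inside), 11L)
  }
  ## a band-range label splits its genes across the two bands
  g19 <- cat[grepl("^C19Q13", S4Vectors::mcols(cat)$symbol)]
  expect_setequal(unique(S4Vectors::mcols(g19)$band),
                  c("19q13.2", "19q13.31"))
  ## zero background genes -> planted genes only
  catP <- generateGeneCatalog(SimulationConfig(backgroundGenes = 0L))
  expect_equal(length(catP), 3L * cfg@genesPerCluster)
  ## determinism
  expect_identical(as.data.frame(cat),
                   as.data.frame(generateGeneCatalog(cfg)))
})

test_that("planted events follow the configured per-group frequencies", {
  pc <- plantedClusterPresets()
  pc$freq_mrd_pos[1] <- 1.0
  cfg <- SimulationConfig(plantedClusters = pc, backgroundRate = 0,
                          seed = 4L)
  co <- generateCohort(cfg)
  mc <- S4Vectors::mcols(co$calls)
  pos <- co$patients$sample_id[co$patients$mrd_status == "positive"]
  loh <- mc$sample_id[mc$event_type == "cnLOH" &
                        as.character(GenomicRanges::seqnames(co$calls)) ==
                        "chr19"]
  expect_true(all(pos %in% loh))
})

test_that("empirical planted frequencies converge to configured rates", {
  ## Monte-Carlo at n = 5000 against the configured 19q13 rates
  cfg <- SimulationConfig(nMrdPos = 2500L, nMrdNeg = 2500L,
                          backgroundRate = 0, backgroundGenes = 0L,
                          seed = 13L)
  co <- generateCohort(cfg)
  mc <- S4Vectors::mcols(co$calls)
  isLoh19 <- mc$event_type == "cnLOH" &
    as.character(GenomicRanges::seqnames(co$calls)) == "chr19"
  neg <- co$patients$sample_id[co$patients$mrd_status == "negative"]
  fNeg <- mean(neg %in% mc$sample_id[isLoh19])
  se <- sqrt(0.16 * 0.84 / 2500)
  expect_lt(abs(fNeg - 0.16), 4 * se)
  pos <- co$patients$sample_id[co$patients$mrd_status == "positive"]
  fPos <- mean(pos %in% mc$sample_id[isLoh19])
  expect_lt(abs(fPos - 0.70), 4 * sqrt(0.7 * 0.3 / 2500))
})

test_that("no planted clusters and zero background rate yields no segments", {
  cfg <- SimulationConfig(plantedClusters = plantedClusterPresets()[0, ],
                          backgroundRate = 0, seed = 1L)
  co <- generateCohort(cfg)
  expect_length(co$calls, 0L)
})

test_that("all generated segments pass QC with default thresholds", {
  for (s in c(1L, 21L, 33L)) {
    sim <- simulateStudy(SimulationConfig(seed = s))
    expect_length(qcFilter(sim$patientCalls), length(sim$patientCalls))
    expect_length(qcFilter(sim$referenceCalls), length(sim$referenceCalls))
  }
})

test_that("reference pool copies patient sexes with jittered ages", {
  cfg <- SimulationConfig(seed = 6L)
  co <- generateCohort(cfg)
  pool <- generateReferencePool(cfg, co$patients)
  expect_equal(nrow(pool$references), 3L * nrow(co$patients))
  expect_identical(pool$references$sex, rep(co$patients$sex, each = 3L))
  expect_true(all(abs(pool$references$age -
                        rep(co$patients$age, each = 3L)) <= 2L))
  ## reference frequency honoured at large n
  big <- SimulationConfig(nMrdPos = 600L, nMrdNeg = 600L,
                          referenceMultiplier = 1L, backgroundRate = 0,
                          backgroundGenes = 0L, seed = 8L)
  bco <- generateCohort(big)
  bpool <- generateReferencePool(big, bco$patients)
  mc <- S4Vectors::mcols(bpool$calls)
  f <- mean(bpool$references$sample_id %in%
              mc$sample_id[mc$event_type == "cnLOH"])
  expect_lt(abs(f - 0.47), 4 * sqrt(0.47 * 0.53 / 1200))
})

test_that("invalid configurations are rejected", {
  pc <- plantedClusterPresets()
  pc$freq_mrd_pos[1] <- 1.2
  expect_error(SimulationConfig(plantedClusters = pc), "\\[0, 1\\]")
  pc <- plantedClusterPresets()
  pc$start[2] <- pc$start[1]
  pc$end[2] <- pc$end[1]
  pc$chrom[2] <- pc$chrom[1]
  expect_error(SimulationConfig(plantedClusters = pc), "overlap")
  expect_error(SimulationConfig(referenceMultiplier = 0L), "Multiplier|>= 1")
})

test_that("simulated studies round-trip through the file dialects", {
  sim <- simulateStudy(SimulationConfig(seed = 17L))
  dir <- withr::local_tempdir()
  paths <- writeSimulation(sim, dir)
  expect_identical(grdf(readSegments(paths[["segments"]])),
                   grdf(sim$patientCalls))
  expect_identical(grdf(readGeneCatalog(paths[["catalog"]])),
                   grdf(sim$catalog))
  samples <- readSamples(paths[["samples"]])
  expect_equal(samples[samples$cohort == "patient", ],
               sim$patients, ignore_attr = TRUE)
})
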