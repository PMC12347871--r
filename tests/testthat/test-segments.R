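## Segment/catalog IO and the QC + landscape filters.

writeSegFile <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(paste(c("sample_id", "chrom", "start", "end", "event_type",
                       "marker_count", "mean_log2ratio", "mosaic_fraction"),
                     collapse = "\t"), rows), path)
  path
}

test_that("readSegments parses the documented dialect", {
  p <- writeSegFile(c(
    "P01\tchr19\t39000000\t40500000\tcnLOH\t195\t.\t.",
    "P01\tchr7\t100000\t900000\tLOSS_MOSAIC\t120\t-0.41\t0.37",
    "P02\tchr1\t5000000\t6000000\tGain\t80\t0.35\t."))
  calls <- readSegments(p)
  expect_s4_class(calls, "AberrationCalls")
  expect_length(calls, 3L)
  mc <- S4Vectors::mcols(calls)
  expect_equal(mc$event_type, c("cnLOH", "loss_mosaic", "gain"))
  expect_equal(segmentSizeKb(calls)[1], 1500.001)
  expect_true(is.na(mc$mean_log2ratio[1]))
  expect_equal(mc$mosaic_fraction[2], 0.37)
})

test_that("readSegments rejects malformed rows with useful errors", {
  expect_error(readSegments(writeSegFile(
    "P01\tchr1\t100\t200\tloss\t-5\t-0.4\t.")), "marker_count")
  expect_error(readSegments(writeSegFile(
    "P01\tchr1\tabc\t200\tloss\t20\t-0.4\t.")), "line 2")
  expect_error(readSegments(writeSegFile(
    "P01\tchr1\t100\t200\tduplication\t20\t0.4\t.")), "duplication")
  ## missing column
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tchrom\tstart\tend\tevent_type\tmarker_count", path)
  expect_error(readSegments(path), "mean_log2ratio")
  expect_error(readSegments(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("segment write/read round-trips generator output exactly", {
  sim <- simulateStudy(SimulationConfig(seed = 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSegments(sim$patientCalls, path)
  back <- readSegments(path)
  expect_identical(grdf(back),
                   grdf(sim$patientCalls))
})

test_that("qcFilter applies the per-class validity rules", {
  calls <- AberrationCalls(
    sample_id = sprintf("P%02d", 1:6), chrom = "chr1",
    start = rep(1e6, 6), end = rep(2e6, 6),
    event_type = c("cnLOH", "cnLOH", "loss", "loss", "gain", "gain"),
    marker_count = c(49L, 50L, 20L, 19L, 60L, 60L),
    mean_log2ratio = c(NA, NA, -0.30, -0.30, 0.10, 0.26))
  kept <- qcFilter(calls)
  expect_equal(S4Vectors::mcols(kept)$sample_id, c("P02", "P03", "P06"))
  ## marker thresholds are inclusive, log2-ratio bound strict
  expect_equal(S4Vectors::mcols(kept)$marker_count[2], 20L)
})

test_that("qcFilter is a pure idempotent selection and flags missing log2R", {
  sim <- generateCohort(SimulationConfig(seed = 5L))
  once <- qcFilter(sim$calls)
  expect_identical(as.data.frame(qcFilter(once)), as.data.frame(once))
  ## retained segments appear unaltered and in input order
  key <- function(x) do.call(paste, as.data.frame(x))
  idx <- match(key(once), key(sim$calls))
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) > 0))
  bad <- AberrationCalls(sample_id = "P01", chrom = "chr1", start = 1e6,
                         end = 2e6, event_type = "loss", marker_count = 30L,
                         mean_log2ratio = NA_real_)
  expect_error(qcFilter(bad), "mean_log2ratio")
})

test_that("landscapeFilter keeps only segments exceeding the size cutoffs", {
  calls <- AberrationCalls(
    sample_id = rep("P01", 4), chrom = "chr2",
    start = c(1e6, 1e6, 1e6, 1e6),
    end = c(1e6 + 499000 - 1, 1e6 + 500001 - 1, 1e6 + 5001000 - 1,
            1e6 + 5000000 - 1),
    event_type = c("loss", "loss", "cnLOH", "cnLOH"),
    marker_count = c(100L, 100L, 700L, 700L),
    mean_log2ratio = c(-0.4, -0.4, NA, NA))
  kept <- landscapeFilter(calls)
  expect_equal(segmentSizeKb(kept), c(500.001, 5001))
  expect_length(landscapeFilter(AberrationCalls()), 0L)
})

test_that("landscapeFilter is a monotone subset in its thresholds", {
  sim <- generateCohort(SimulationConfig(seed = 9L))
  calls <- qcFilter(sim$calls)
  loose <- landscapeFilter(calls, QCThresholds(minCnvKbLandscape = 100,
                                               minLohKbLandscape = 1000))
  strict <- landscapeFilter(calls, QCThresholds(minCnvKbLandscape = 2000,
                                                minLohKbLandscape = 20000))
  expect_lte(length(loose), length(calls))
  expect_lte(length(strict), length(loose))
  ## subset relation against the input
  key <- function(x) do.call(paste, as.data.frame(x))
  expect_true(all(key(strict) %in% key(calls)))
})

test_that("gene catalog BED interchange converts coordinates and validates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr19\t100\t200\tGENEA\t19q13.2",
               "chr19\t300\t450\tGENEB\t19q13.31"), path)
  cat <- readGeneCatalog(path)
  expect_equal(GenomicRanges::start(cat), c(101L, 301L))
  expect_equal(GenomicRanges::end(cat), c(200L, 450L))
  ## round trip back to BED semantics
  out <- withr::local_tempfile(fileext = ".bed")
  writeGeneCatalog(cat, out)
  expect_identical(readLines(out), readLines(path))
  writeLines(c("chr19\t100\t200\tPSG1\t19q13.2",
               "chr19\t300\t450\tPSG1\t19q13.2"), path)
  expect_error(readGeneCatalog(path), "duplicate")
  writeLines("chr19\t200\t200\tGENEA\t19q13.2", path)
  expect_error(readGeneCatalog(path), "invalid BED")
  file.create(empty <- withr::local_tempfile(fileext = ".bed"))
  expect_length(readGeneCatalog(empty), 0L)
})
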