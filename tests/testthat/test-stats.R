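## Contingency statistics, Fisher exact test, odds ratios, BH correction,
## frequencies, cluster detection and region summaries.

## tiny GeneEventMatrix straight from per-group carrier counts
countsGem <- function(aPos, nPos, cNeg, nNeg, feature = "G1:cnLOH") {
  m <- matrix(c(rep(1L, aPos), rep(0L, nPos - aPos),
                rep(1L, cNeg), rep(0L, nNeg - cNeg)), nrow = 1,
              dimnames = list(feature, sprintf("S%02d", seq_len(nPos + nNeg))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = m),
    rowData = S4Vectors::DataFrame(
      symbol = sub(":.*$", "", feature), event = sub("^.*:", "", feature),
      band = "19q13.2", row.names = feature))
  list(gem = methods::new("GeneEventMatrix", se),
       labels = rep(c("positive", "negative"), c(nPos, nNeg)))
}

test_that("featureContingency counts carriers per MRD group", {
  f <- countsGem(13, 17, 3, 18)
  expect_equal(featureContingency(f$gem, f$labels, "G1:cnLOH"),
               c(a = 13L, b = 4L, c = 3L, d = 15L))
  z <- countsGem(0, 17, 0, 18)
  expect_equal(featureContingency(z$gem, z$labels, "G1:cnLOH"),
               c(a = 0L, b = 17L, c = 0L, d = 18L))
  o <- countsGem(17, 17, 18, 18)
  expect_equal(featureContingency(o$gem, o$labels, "G1:cnLOH"),
               c(a = 17L, b = 0L, c = 18L, d = 0L))
  expect_error(featureContingency(f$gem, f$labels, "NOPE:loss"), "unknown")
})

test_that("fisherExact reproduces enumeration-oracle values", {
  ## frozen from the lchoose enumeration oracle
  expect_equal(fisherExact(13, 4, 3, 15), 0.0006105451673, tolerance = 1e-9)
  expect_equal(fisherExact(0, 17, 0, 18), 1)
  ## single most-extreme table on each side: both tie, p = 2 / C(20,10)
  expect_equal(fisherExact(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisherExact(6, 11, 1, 17), 0.0407523511, tolerance = 1e-9)
  expect_error(fisherExact(-1, 2, 3, 4), "non-negative")
})

test_that("fisherExact agrees with stats::fisher.test on random tables", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    expect_equal(fisherExact(a, b, c, d),
                 stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
  }
})

test_that("oddsRatio uses the cross product with zero-cell correction", {
  expect_equal(oddsRatio(13, 4, 3, 15), 16.25)
  expect_equal(oddsRatio(6, 11, 1, 17), 102 / 11, tolerance = 1e-12)
  ## Haldane-Anscombe on any zero cell
  expect_equal(oddsRatio(0, 17, 3, 15), (0.5 * 15.5) / (17.5 * 3.5))
  ## inversion symmetry for strictly positive cells
  expect_equal(oddsRatio(5, 7, 2, 9) * oddsRatio(7, 5, 9, 2), 1)
})

test_that("adjustPvalues applies BH step-up and preserves order", {
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(0.2), 0.2)
  expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(50)
  q <- adjustPvalues(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_error(adjustPvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("groupFrequencies handles reference and edge cases", {
  f <- countsGem(13, 17, 3, 18)
  fr <- groupFrequencies(f$gem, f$labels)
  expect_equal(fr$freq_mrd_pos, 13 / 17)
  expect_equal(fr$freq_mrd_neg, 3 / 18)
  ## feature absent from the reference matrix -> reference frequency 0
  ref <- countsGem(4, 5, 4, 5, feature = "OTHER:gain")
  fr2 <- groupFrequencies(f$gem, f$labels, refGem = ref$gem)
  expect_equal(fr2$freq_reference, 0)
  ## single-sample group carrier -> frequency 1
  g1 <- countsGem(1, 1, 0, 3)
  expect_equal(groupFrequencies(g1$gem, g1$labels)$freq_mrd_pos, 1)
  expect_error(groupFrequencies(f$gem, rep("positive", 35)), "single class")
})

test_that("featureStats combines counts, OR, Fisher p and q-values", {
  sim <- simulateStudy(SimulationConfig(seed = 41L))
  gem <- encodeGeneEvents(qcFilter(sim$patientCalls), sim$catalog,
                          sim$patients$sample_id, colData = sim$patients)
  st <- featureStats(gem, mrdLabels(gem))
  expect_equal(st$a + st$b, rep(17L, nrow(st)), ignore_attr = TRUE)
  expect_equal(st$c + st$d, rep(18L, nrow(st)), ignore_attr = TRUE)
  expect_true(all(st$q_adj >= st$p_raw - 1e-12))
  expect_true(all(is.finite(st$odds_ratio)))
  expect_equal(st$p_raw, fisherExact(st$a, st$b, st$c, st$d))
  ## sorted by raw p
  expect_true(all(diff(st$p_raw) >= -1e-12))
})

test_that("type-I error of the univariate screen is controlled under null", {
  ## labels independent of all features: pooled fraction of p <= 0.05
  ps <- unlist(lapply(1:8, function(s) {
    sim <- simulateStudy(nullSimConfig(seed = 100L + s, n = 10L))
    gem <- encodeGeneEvents(qcFilter(sim$patientCalls), sim$catalog,
                            sim$patients$sample_id, colData = sim$patients)
    featureStats(gem, mrdLabels(gem))$p_raw
  }))
  expect_gt(length(ps), 100)
  expect_lte(mean(ps <= 0.05), 0.06)   # Fisher is discrete, conservative
})

test_that("detectClusters chains same-event contiguous genes", {
  cat <- GeneCatalog(symbol = sprintf("G%02d", 1:8), chrom = "chr1",
                     start = 1e6 + (0:7) * 5e5, end = 1e6 + (0:7) * 5e5 + 1e4,
                     band = "1p36")
  feats <- sprintf("G%02d:loss", 1:8)
  cl <- detectClusters(feats, cat, minGenes = 5L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_genes, 8L)
  expect_equal(cl$event, "loss")
  expect_equal(cl$label, "1p36")
  ## order invariance
  cl2 <- detectClusters(rev(feats), cat, minGenes = 5L)
  expect_identical(cl, cl2)
  ## mixed events never chain together
  mixed <- c(sprintf("G%02d:loss", 1:4), sprintf("G%02d:gain", 5:8))
  expect_equal(nrow(detectClusters(mixed, cat, minGenes = 5L)), 0L)
  ## a > maxGap hole splits the chain below minGenes
  cat2 <- GeneCatalog(symbol = sprintf("G%02d", 1:8), chrom = "chr1",
                      start = c(1e6 + (0:3) * 5e5, 2e7 + (0:3) * 5e5),
                      end = c(1e6 + (0:3) * 5e5, 2e7 + (0:3) * 5e5) + 1e4,
                      band = "1p36")
  expect_equal(nrow(detectClusters(feats, cat2, minGenes = 5L)), 0L)
  expect_equal(nrow(detectClusters(feats, cat2, minGenes = 4L)), 2L)
  expect_error(detectClusters("NOPE:loss", cat), "missing from catalog")
})

test_that("regionSummary reports min/median/max per group", {
  cat <- GeneCatalog(symbol = sprintf("R%02d", 1:22), chrom = "chr19",
                     start = 39e6 + (0:21) * 45000,
                     end = 39e6 + (0:21) * 45000 + 20000,
                     band = "19q13.2")
  seg <- AberrationCalls(sample_id = "P01", chrom = "chr19", start = 39e6,
                         end = 39e6 + 1045830 - 1, event_type = "cnLOH",
                         marker_count = 89L)
  rs <- regionSummary(seg, "chr19:39000000-40500000", "cnLOH", cat,
                      groups = list(mrd_pos = "P01"))
  expect_equal(rs$min, rs$max)
  expect_equal(rs$min, rs$median)
  expect_equal(rs[rs$statistic == "size_kb", "min"], 1045.83)
  expect_equal(rs[rs$statistic == "marker_count", "min"], 89)
  expect_equal(rs[rs$statistic == "gene_count", "min"], 22)
  ## median over three segments of 1, 2, 3 Mb
  seg3 <- AberrationCalls(sample_id = rep("P01", 3), chrom = "chr19",
                          start = rep(39e6, 3),
                          end = 39e6 + c(1e6, 2e6, 3e6) - 1,
                          event_type = "cnLOH",
                          marker_count = c(100L, 200L, 300L))
  rs3 <- regionSummary(seg3, "chr19:39000000-40500000", "cnLOH", cat,
                       groups = list(g = "P01"))
  expect_equal(rs3[rs3$statistic == "size_kb", "median"], 2000)
  expect_error(
    regionSummary(seg, "chr19:39000000-40500000", "cnLOH", cat,
                  groups = list(ref = "R999")), "group 'ref'")
})
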