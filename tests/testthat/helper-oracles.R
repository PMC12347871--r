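## Independent oracles and small fixture builders shared across tests.

## Canonical data.frame view of a GRanges-based object for equality checks
## (drops width/strand, normalises seqnames factor levels and rownames).
grdf <- function(x) {
  df <- as.data.frame(x)
  df$seqnames <- as.character(df$seqnames)
  df$width <- NULL
  df$strand <- NULL
  rownames(df) <- NULL
  df
}

## Exhaustive two-sided Fisher p by direct enumeration of all tables with
## the observed margins, point probabilities from log-binomial coefficients
## (independent of the package's dhyper-based route). The same relative
## tolerance is used for floating-point ties between point probabilities.
enumFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  supp <- max(0, k - r2):min(r1, k)
  pr <- exp(lchoose(r1, supp) + lchoose(r2, k - supp) - lchoose(n, k))
  pobs <- exp(lchoose(r1, a) + lchoose(r2, k - a) - lchoose(n, k))
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

## Brute-force gene:event encoding by a double loop over all segment x gene
## pairs with plain coordinate arithmetic (no GRanges machinery).
bruteForceEncode <- function(calls, catalog, samples) {
  mc <- as.data.frame(calls)
  cat <- as.data.frame(catalog)
  hits <- character(0)
  hitSample <- character(0)
  for (i in seq_len(nrow(mc))) {
    ev <- if (mc$event_type[i] == "loss_mosaic") "loss" else mc$event_type[i]
    for (j in seq_len(nrow(cat))) {
      if (as.character(mc$seqnames[i]) == as.character(cat$seqnames[j]) &&
          max(mc$start[i], cat$start[j]) <= min(mc$end[i], cat$end[j])) {
        hits <- c(hits, paste0(cat$symbol[j], ":", ev))
        hitSample <- c(hitSample, mc$sample_id[i])
      }
    }
  }
  feats <- sort(unique(hits), method = "radix")
  m <- matrix(0L, length(feats), length(samples),
              dimnames = list(feats, samples))
  for (k in seq_along(hits)) m[hits[k], hitSample[k]] <- 1L
  m
}

## 35-sample, single-feature matrix from the published 19q13 carrier
## counts: 13 of 17 MRD-positive and 3 of 18 MRD-negative carriers.
tableOneMatrix <- function() {
  x <- matrix(c(rep(1, 13), rep(0, 4), rep(1, 3), rep(0, 15)), ncol = 1,
              dimnames = list(sprintf("S%02d", 1:35), "C19Q13:cnLOH"))
  list(x = x, labels = rep(c("positive", "negative"), c(17, 18)))
}

## Small no-signal simulation: planted clusters at identical frequencies in
## both MRD groups, so labels are independent of all features.
nullSimConfig <- function(seed, n = 10L) {
  pc <- plantedClusterPresets()
  pc$freq_mrd_pos <- 0.3
  pc$freq_mrd_neg <- 0.3
  pc$freq_reference <- 0.3
  SimulationConfig(nMrdPos = n, nMrdNeg = n, backgroundRate = 2,
                   backgroundGenes = 100L, plantedClusters = pc,
                   seed = seed)
}

## Random feasible triple assignment (same-sex, without replacement), used
## as the baseline the greedy matcher must beat on mean |age difference|.
randomAssignment <- function(patients, pool) {
  total <- 0
  for (s in unique(patients$sex)) {
    pidx <- which(patients$sex == s)
    ridx <- sample(which(pool$sex == s))
    for (i in seq_along(pidx)) {
      picks <- ridx[(3 * i - 2):(3 * i)]
      total <- total + sum(abs(pool$age[picks] - patients$age[pidx[i]]))
    }
  }
  total / (3 * nrow(patients))
}
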