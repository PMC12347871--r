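#' Triple sex/age-matched reference assignment
#'
#' Assigns every patient exactly three reference individuals of the same
#' sex, minimising age differences greedily: patients are processed in
#' lexicographic id order and each receives the three still-unassigned
#' same-sex pool members with the smallest absolute age difference (ties
#' broken by reference id). Assignment is without replacement, so no
#' reference serves two patients. Matching uses demographic fields only —
#' never aberration data — to avoid selection leakage. The procedure is
#' deterministic.
#'
#' @param patients data.frame with columns \code{sample_id}, \code{sex},
#'   \code{age}.
#' @param pool data.frame of reference candidates with the same columns.
#' @return A \linkS4class{MatchedReference}.
#' @examples
#' pats <- data.frame(sample_id = "P1", sex = "M", age = 30)
#' pool <- data.frame(sample_id = paste0("R", 1:3), sex = "M",
#'                    age = c(29, 30, 33))
#' matchQuality(matchTriple(pats, pool))  # mean |age diff| = 4/3
#' @export
matchTriple <- function(patients, pool) {
  need <- c("sample_id", "sex", "age")
  stopifnot(all(need %in% colnames(patients)), all(need %in% colnames(pool)))
  if (nrow(pool) < 3L * nrow(patients))
    stop(sprintf("pool has %d members; %d patients need %d",
                 nrow(pool), nrow(patients), 3L * nrow(patients)))
  ## global sex feasibility before any assignment
  for (s in unique(patients$sex)) {
    needS <- 3L * sum(patients$sex == s)
    haveS <- sum(pool$sex == s)
    if (haveS < needS)
      stop(sprintf("pool sex-exhausted: %d references of sex %s for %d needed",
                   haveS, s, needS))
  }
  used <- rep(FALSE, nrow(pool))
  rows <- lapply(lexSort(patients$sample_id), function(pid) {
    p <- patients[patients$sample_id == pid, ][1, ]
    avail <- which(!used & pool$sex == p$sex)
    if (length(avail) < 3L)
      stop("pool exhausted while matching patient ", pid)
    diffs <- abs(pool$age[avail] - p$age)
    pick <- avail[order(diffs, pool$sample_id[avail], method = "radix")][1:3]
    used[pick] <<- TRUE
    data.frame(patient_id = pid, ref_id = pool$sample_id[pick],
               age_diff = as.integer(abs(pool$age[pick] - p$age)),
               stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, rows)
  methods::new("MatchedReference", assignments = a,
               quality = mean(a$age_diff))
}

#' Compare aberration frequencies with the reference cohort
#'
#' Per feature: carrier frequency among patients and among references, and
#' a two-sided Fisher exact p for the carrier-count difference between the
#' two cohorts. The feature dictionaries are merged (union); a feature
#' absent from one matrix counts zero carriers there.
#'
#' @param gem patient \linkS4class{GeneEventMatrix}.
#' @param refGem reference \linkS4class{GeneEventMatrix}.
#' @param features feature ids to compare (default: union of both
#'   dictionaries).
#' @return data.frame with columns \code{feature_id}, \code{freq_patient},
#'   \code{freq_reference}, \code{p_fisher}, sorted by p then id.
#' @export
compareWithReference <- function(gem, refGem, features = NULL) {
  stopifnot(is(gem, "GeneEventMatrix"), is(refGem, "GeneEventMatrix"))
  if (ncol(gem) == 0L || ncol(refGem) == 0L)
    stop("both cohorts must be non-empty")
  if (is.null(features))
    features <- lexSort(union(rownames(gem), rownames(refGem)))
  carriers <- function(g, f) {
    m <- presenceMatrix(g)
    out <- integer(length(f))
    hit <- f %in% rownames(m)
    out[hit] <- rowSums(m[f[hit], , drop = FALSE])
    out
  }
  cp <- carriers(gem, features)
  cr <- carriers(refGem, features)
  np <- ncol(gem)
  nr <- ncol(refGem)
  p <- fisherExact(cp, np - cp, cr, nr - cr)
  out <- data.frame(feature_id = features, freq_patient = cp / np,
                    freq_reference = cr / nr, p_fisher = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_fisher, out$feature_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
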