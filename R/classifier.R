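## Random-forest scoring, impurity-based feature ranking and the
## label-permutation significance test. Forests are grown with ranger,
## single-threaded and explicitly seeded, so every result is reproducible.

.featureMatrix <- function(x) {
  if (is(x, "GeneEventMatrix")) {
    m <- t(presenceMatrix(x))
  } else if (is.matrix(x)) {
    m <- x
  } else stop("x must be a GeneEventMatrix or a samples-by-features matrix")
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%04d", seq_len(ncol(m)))
  m
}

.checkLabels <- function(labels, n, nFolds = NULL) {
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must align with the sample order of the matrix (",
         length(labels), " labels for ", n, " samples)")
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("labels contain a single class; a two-class outcome is required")
  if (length(tab) > 2L)
    stop("more than two classes in labels: ",
         paste(names(tab), collapse = ", "))
  if (!is.null(nFolds) && nFolds > min(tab))
    stop(sprintf(paste0("nFolds (%d) exceeds the smallest class count (%d);",
                        " stratified folds would leave some test folds",
                        " without that class"), nFolds, min(tab)))
  labels
}

## stratified fold assignment: per class, shuffle then deal round-robin,
## so fold sizes and class proportions stay as balanced as possible
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated random-forest accuracy
#'
#' Mean accuracy over \code{nFolds} stratified cross-validation folds of a
#' random-forest classifier (per-fold class proportions are preserved; with
#' a 17/18 class split, unstratified 10-fold assignment could produce
#' single-class test folds). The reported value is the unweighted mean of
#' the per-fold accuracies. Fully reproducible given \code{config@seed}.
#'
#' @param x a \linkS4class{GeneEventMatrix}, or a samples-by-features
#'   numeric matrix.
#' @param labels two-class outcome vector aligned with the matrix sample
#'   order (for MRD analyses, \code{"positive"}/\code{"negative"}).
#' @param config a \linkS4class{ModelConfig}.
#' @return mean fold accuracy in [0, 1].
#' @export
cvAccuracy <- function(x, labels, config = ModelConfig()) {
  stopifnot(is(config, "ModelConfig"))
  m <- .featureMatrix(x)
  labels <- .checkLabels(labels, nrow(m), config@nFolds)
  y <- factor(labels)
  withSeed(config@seed, {
    fold <- .stratifiedFolds(labels, config@nFolds)
    acc <- vapply(seq_len(config@nFolds), function(f) {
      tr <- fold != f
      fit <- ranger::ranger(x = m[tr, , drop = FALSE], y = y[tr],
                            num.trees = config@nTrees,
                            seed = config@seed + f, num.threads = 1L)
      pred <- predict(fit, data = m[!tr, , drop = FALSE],
                      num.threads = 1L)$predictions
      mean(pred == y[!tr])
    }, numeric(1))
    mean(acc)
  })
}

#' Impurity-based feature ranking
#'
#' Grows one forest on all samples and ranks features by normalized Gini
#' (impurity-decrease) importance; importances over the full feature set
#' sum to 1, ties are broken lexicographically by feature id, and the top
#' \code{config@topK} rows are returned. Because impurity importance is
#' unsigned, each feature's direction is annotated from raw group carrier
#' frequencies: \code{risk} if the feature is more frequent among
#' MRD-positive samples, \code{favorable} otherwise.
#'
#' @inheritParams cvAccuracy
#' @param positiveClass label value treated as the MRD-positive group.
#' @return data.frame with columns \code{feature_id}, \code{importance},
#'   \code{rank}, \code{direction}, \code{freq_mrd_pos},
#'   \code{freq_mrd_neg}.
#' @export
rankFeatures <- function(x, labels, config = ModelConfig(),
                         positiveClass = "positive") {
  stopifnot(is(config, "ModelConfig"))
  m <- .featureMatrix(x)
  labels <- .checkLabels(labels, nrow(m), config@nFolds)
  if (!positiveClass %in% labels)
    stop("positiveClass '", positiveClass, "' not present in labels")
  fit <- ranger::ranger(x = m, y = factor(labels),
                        num.trees = config@nTrees, importance = "impurity",
                        seed = config@seed, num.threads = 1L)
  imp <- fit$variable.importance
  s <- sum(imp)
  imp <- if (s > 0) imp / s else rep(1 / length(imp), length(imp))
  pos <- labels == positiveClass
  freqPos <- colMeans(m[pos, , drop = FALSE])
  freqNeg <- colMeans(m[!pos, , drop = FALSE])
  ord <- order(-imp, colnames(m), method = "radix")
  out <- data.frame(
    feature_id = colnames(m)[ord],
    importance = unname(imp[ord]),
    rank = seq_along(ord),
    direction = ifelse(freqPos[ord] > freqNeg[ord], "risk", "favorable"),
    freq_mrd_pos = unname(freqPos[ord]),
    freq_mrd_neg = unname(freqNeg[ord]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[seq_len(min(nrow(out), config@topK)), , drop = FALSE]
}

#' Label-permutation significance test for classifier accuracy
#'
#' Recomputes the cross-validated accuracy under \code{nPermutations}
#' random shuffles of the class labels (the feature matrix is fixed, so the
#' class balance is preserved exactly) to form an empirical null
#' distribution, and reports the add-one p-value
#' \eqn{(1 + \#\{null \ge observed\})/(B + 1)}. With 1000 permutations and
#' an observed accuracy above the entire null, p = 1/1001, printed as
#' 0.001; the estimator never returns 0.
#'
#' @inheritParams cvAccuracy
#' @return A \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(x, labels, config = ModelConfig()) {
  stopifnot(is(config, "ModelConfig"))
  m <- .featureMatrix(x)
  labels <- .checkLabels(labels, nrow(m), config@nFolds)
  observed <- cvAccuracy(m, labels, config)
  B <- config@nPermutations
  nulls <- numeric(B)
  withSeed(config@seed, {
    for (b in seq_len(B)) {
      shuffled <- sample(labels)
      cfg <- config
      cfg@seed <- config@seed + b
      nulls[b] <- cvAccuracy(m, shuffled, cfg)
    }
  })
  PermutationResult(observed, nulls)
}

#' Plot the permutation null distribution
#'
#' Histogram of null accuracies with the observed accuracy as a dashed
#' vertical line.
#'
#' @param x a \linkS4class{PermutationResult}.
#' @param ... passed to \code{\link[graphics]{hist}}.
#' @return \code{x}, invisibly.
#' @importFrom graphics hist abline legend
#' @export
plotNullDistribution <- function(x, ...) {
  stopifnot(is(x, "PermutationResult"))
  graphics::hist(x@nulls, breaks = 30,
                 xlim = range(c(x@nulls, x@observed)),
                 main = "Permutation null distribution",
                 xlab = "cross-validated accuracy", col = "grey80", ...)
  graphics::abline(v = x@observed, col = "red3", lty = 2, lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("observed = %.3f (p = %.3g)",
                                    x@observed, x@pValue))
  invisible(x)
}
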