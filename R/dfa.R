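#' Fit a quadratic discriminant model
#'
#' Class-conditional Gaussian model over the six envelope statistics: per-
#' class means and population-normalized (1/n) covariance matrices with a
#' small ridge (`ridge * mean(diag(S))` added to the diagonal) to guard
#' against singular covariances, and class priors proportional to class
#' frequency. Prediction is the argmax of the quadratic discriminant score
#' `-0.5 log|S_k| - 0.5 (x-mu_k)' S_k^-1 (x-mu_k) + log prior_k`. The
#' population normalization makes the fitted model an exact function of the
#' per-class means and covariances: duplicating every training sample leaves
#' predictions unchanged.
#'
#' @param x Numeric matrix, one row per sample.
#' @param labels Class labels (coerced to factor).
#' @param ridge Ridge fraction (default 1e-6).
#' @return A [QDAModel-class].
#' @export
fitQda <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- factor(labels)
  labels <- droplevels(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 samples to estimate a covariance")
  cls <- levels(labels)
  means <- covs <- vector("list", length(cls))
  names(means) <- names(covs) <- cls
  for (k in cls) {
    xk <- x[labels == k, , drop = FALSE]
    means[[k]] <- colMeans(xk)
    S <- stats::cov(xk) * (nrow(xk) - 1) / nrow(xk)
    covs[[k]] <- S + diag(ridge * mean(diag(S)), ncol(x))
  }
  priors <- stats::setNames(as.numeric(counts) / length(labels), cls)
  new("QDAModel", means = means, covariances = covs, priors = priors,
      ridge = ridge,
      featureNames = colnames(x) %||% paste0("f", seq_len(ncol(x))))
}

#' Predict classes with a quadratic discriminant model
#'
#' @param model A [QDAModel-class].
#' @param x Numeric matrix, one row per sample, columns in training order.
#' @return Character vector of predicted class labels.
#' @export
predictQda <- function(model, x) {
  stopifnot(is(model, "QDAModel"))
  x <- as.matrix(x)
  cls <- names(model@means)
  scores <- vapply(cls, function(k) {
    mu <- model@means[[k]]
    ch <- chol(model@covariances[[k]])
    z <- backsolve(ch, t(x) - mu, transpose = TRUE)
    -sum(log(diag(ch))) - 0.5 * colSums(z^2) + log(model@priors[[k]])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L)
  cls[max.col(scores, ties.method = "first")]
}

#' Cross-validated discriminant classification of envelope features
#'
#' Runs the study's protocol on the six-feature table: in each of `nRepeats`
#' repeats a random `testFraction` of the echoes is held out, echoes of the
#' same individual within `exclusionHalfwidth` angular positions of any test
#' echo are excluded from training, a quadratic discriminant model is fitted
#' on the remainder, and the held-out echoes are scored. The per-species
#' accuracy of a repeat is the per-class recall (fraction of that species'
#' test echoes correctly labeled), in percent. Chance for the balanced
#' three-species task is 33.3%.
#'
#' @param features [S4Vectors::DataFrame] or data.frame from [featureTable()]
#'   (must contain `species`, `individual`, `angleIndex` and the feature
#'   columns).
#' @param featureNames Feature columns to use (default the six statistics).
#' @param nAngles Positions on the rotation grid (default inferred as
#'   `max(angleIndex) + 1`).
#' @param nRepeats,testFraction,exclusionHalfwidth Cross-validation
#'   parameters (defaults 10, 0.1, 2).
#' @param chance Chance level in percent (default 100/3).
#' @param ridge Ridge fraction for [fitQda()].
#' @param seed Seed for the test-set draws.
#'
#' @return Named list of [ClassificationResult-class], one per species.
#' @export
crossvalidateDfa <- function(features,
                             featureNames = c("m2", "m3n", "m4n", "crest", "A", "b"),
                             nAngles = NULL, nRepeats = 10, testFraction = 0.1,
                             exclusionHalfwidth = 2, chance = 100 / 3,
                             ridge = 1e-6, seed = 1) {
  meta <- as.data.frame(features[, c("species", "individual", "angleIndex")])
  x <- as.matrix(as.data.frame(features[, featureNames, drop = FALSE]))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (is.null(nAngles)) nAngles <- max(meta$angleIndex) + 1L
  species <- sort(unique(meta$species))
  splits <- makeCvSplits(meta, nAngles, nRepeats, testFraction,
                         exclusionHalfwidth, seed)
  acc <- matrix(NA_real_, nRepeats, length(species),
                dimnames = list(NULL, species))
  for (r in seq_len(nRepeats)) {
    sp <- splits[[r]]
    trainLab <- meta$species[sp$train]
    if (any(table(factor(trainLab, levels = species)) == 0L))
      stop("adjacent-echo exclusion left a species with no training echoes")
    model <- fitQda(x[sp$train, , drop = FALSE], trainLab, ridge)
    pred <- predictQda(model, x[sp$test, , drop = FALSE])
    truth <- meta$species[sp$test]
    for (s in species) {
      sel <- truth == s
      if (any(sel)) acc[r, s] <- 100 * mean(pred[sel] == s)
    }
  }
  out <- lapply(species, function(s)
    classResult(paste0("dfa:", s), acc[, s], chance))
  names(out) <- species
  out
}

#' Discriminant classification after leaving one feature out
#'
#' Re-runs [crossvalidateDfa()] on five of the six envelope statistics. The
#' importance of the left-out feature is the accuracy drop relative to the
#' full model run with the same seed.
#'
#' @inheritParams crossvalidateDfa
#' @param leaveOut Name of the feature to exclude (one of the six).
#' @return Named list of [ClassificationResult-class], one per species.
#' @export
featureAblation <- function(features, leaveOut,
                            featureNames = c("m2", "m3n", "m4n", "crest", "A", "b"),
                            ...) {
  if (!leaveOut %in% featureNames)
    stop(sprintf("unknown feature '%s'; expected one of %s", leaveOut,
                 paste(featureNames, collapse = ", ")))
  crossvalidateDfa(features, featureNames = setdiff(featureNames, leaveOut),
                   ...)
}

#' @describeIn QDAModel-class Compact display.
#' @param object A `QDAModel`.
#' @export
setMethod("show", "QDAModel", function(object) {
  cat(sprintf(
    "QDAModel: %d classes (%s), %d features, ridge %.1e\n",
    length(object@means), paste(names(object@means), collapse = ", "),
    length(object@featureNames), object@ridge))
})
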