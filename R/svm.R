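#' Train a linear maximum-margin spectrogram classifier
#'
#' Fits a soft-margin linear support-vector separator: the hyperplane that
#' minimizes the classification error while maximizing the distance to the
#' closest data points. The weight vector `w` (length 930) and the offset `b`
#' are recovered from the support-vector expansion, so the decision rule is
#' exactly `sign(<w, x> + b)`.
#'
#' @param x Numeric matrix of flattened spectrograms, one row per echo, or an
#'   [EchoSpectrogramSet-class] (columns become rows).
#' @param labels Two-level class labels, one per row.
#' @param C Soft-margin penalty (default 1).
#' @param positive Label to map to the positive sign (default the first level
#'   of `factor(labels)`).
#' @param taskType `"pairwise"` or `"one_vs_all"` descriptor stored on the
#'   model.
#'
#' @return A [LinearDecisionModel-class].
#' @export
trainLinearSvm <- function(x, labels, C = 1, positive = NULL,
                           taskType = "pairwise") {
  if (is(x, "EchoSpectrogramSet"))
    x <- t(SummarizedExperiment::assay(x, "spectro"))
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required (got ", nlevels(labels), ")")
  if (is.null(positive)) positive <- levels(labels)[1L]
  negative <- setdiff(levels(labels), positive)
  fit <- e1071::svm(x, labels, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's positive decision values correspond to fit$levels[fit$labels[1]];
  # flip signs if that is not the requested positive class.
  libsvmPositive <- fit$levels[fit$labels[1L]]
  if (libsvmPositive != positive) {
    w <- -w
    b <- -b
  }
  new("LinearDecisionModel", w = as.numeric(w), offset = b, cost = C,
      taskType = taskType, positive = positive, negative = negative)
}

#' Classify spectrograms with a linear decision model
#'
#' Applies the decision rule `sign(<w, x> + offset)`; an inner product of
#' exactly zero is assigned to the positive class.
#'
#' @param model A [LinearDecisionModel-class], or a list with elements `w`
#'   and `offset` (e.g. a smoothed [DecisionEcho-class] via
#'   [decisionRule()]).
#' @param x Flattened spectrogram vector (length 930), matrix with one row
#'   per echo, or an [EchoSpectrogramSet-class].
#' @return Character vector of predicted labels.
#' @export
classifySpectrograms <- function(model, x) {
  stopifnot(is(model, "LinearDecisionModel"))
  if (is(x, "EchoSpectrogramSet"))
    x <- t(SummarizedExperiment::assay(x, "spectro"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@w))
    stop("spectrogram geometry does not match the model weight vector")
  d <- drop(x %*% model@w) + model@offset
  ifelse(d >= 0, model@positive, model@negative)
}

#' Extract the decision echo of a trained linear model
#'
#' Reshapes the weight vector to the 10 x 93 spectrogram geometry. High
#' absolute values mark the spectro-temporal regions most important for the
#' species decision.
#'
#' @param model A [LinearDecisionModel-class].
#' @return A [DecisionEcho-class] (unsmoothed).
#' @export
decisionEcho <- function(model) {
  stopifnot(is(model, "LinearDecisionModel"))
  if (length(model@w) != 930L)
    stop("decision echoes are defined for 930-element spectrogram models")
  new("DecisionEcho", weights = unflattenSpectrogram(model@w),
      offset = model@offset, smoothed = FALSE, kernelSize = 10L,
      kernelSigma = 7, freqAxis = SPECTRO_FREQS,
      timeAxis = (((seq_len(93L) - 1L) * SPECTRO_HOP) + (SPECTRO_WINDOW - 1) / 2) / 1e6)
}

#' Unit-sum truncated 2-D Gaussian smoothing kernel
#'
#' A `size x size` pixel Gaussian with width `sigma` pixels, normalized to
#' sum to 1. With the default 10 x 10 grid and sigma = 7 the Gaussian is
#' strongly truncated; the renormalization keeps the kernel unit-sum. The
#' anchor of the even-sized kernel sits at grid position (5, 5) (half-pixel
#' shift).
#'
#' @param size Kernel side length in pixels (default 10).
#' @param sigma Gaussian width in pixels (default 7).
#' @return A `size x size` matrix summing to 1.
#' @export
gaussianKernel2d <- function(size = 10L, sigma = 7) {
  anchor <- size %/% 2L          # position 5 on a 10-wide grid
  d <- seq_len(size) - anchor
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# 2-D convolution with symmetric (edge-reflecting) border padding and the
# kernel anchored at (anchor, anchor). Preserves constants exactly for any
# unit-sum kernel.
#' @noRd
convolve2dReflect <- function(m, k, anchor = nrow(k) %/% 2L) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  padTop <- anchor - 1L; padBottom <- kr - anchor
  padLeft <- anchor - 1L; padRight <- kc - anchor
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    idx
  }
  ri <- reflect((1L - padTop):(nr + padBottom), nr)
  ci <- reflect((1L - padLeft):(nc + padRight), nc)
  mp <- m[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr))
    for (j in seq_len(kc))
      out <- out + k[i, j] * mp[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}

#' Smooth a decision echo with the unit-sum Gaussian kernel
#'
#' Convolves the weight matrix with the 10 x 10, sigma = 7 pixel Gaussian
#' kernel (normalized to sum 1), handling borders by reflection. Smoothing
#' removes high-frequency structure that may be an artifact of the small
#' sample size; the offset is unchanged so the smoothed rule can be re-scored
#' directly.
#'
#' @param de An unsmoothed [DecisionEcho-class].
#' @param size,sigma Kernel parameters (defaults 10, 7).
#' @return A smoothed [DecisionEcho-class].
#' @export
smoothDecisionEcho <- function(de, size = 10L, sigma = 7) {
  stopifnot(is(de, "DecisionEcho"))
  if (de@smoothed) stop("decision echo is already smoothed")
  k <- gaussianKernel2d(size, sigma)
  new("DecisionEcho", weights = convolve2dReflect(de@weights, k),
      offset = de@offset, smoothed = TRUE, kernelSize = as.integer(size),
      kernelSigma = sigma, freqAxis = de@freqAxis, timeAxis = de@timeAxis)
}

# Model whose weights are replaced by a (possibly smoothed) decision echo.
#' @noRd
modelWithWeights <- function(model, de) {
  new("LinearDecisionModel", w = flattenSpectrogram(de@weights),
      offset = de@offset, cost = model@cost, taskType = model@taskType,
      positive = model@positive, negative = model@negative)
}

# Build binary labels for a task on a spectrogram set.
#' @noRd
taskLabels <- function(species, task) {
  if (task$type == "pairwise") {
    keep <- species %in% task$classes
    list(keep = which(keep), labels = species[keep],
         positive = task$classes[1L], chance = 50,
         name = paste0("pairwise:", paste(task$classes, collapse = "|")))
  } else if (task$type == "one_vs_all") {
    lab <- ifelse(species == task$species, task$species, "rest")
    prop <- mean(lab == task$species)
    list(keep = seq_along(species), labels = lab, positive = task$species,
         chance = 100 * max(prop, 1 - prop),
         name = paste0("one_vs_all:", task$species))
  } else stop("unknown task type: ", task$type)
}

#' Cross-validated max-margin classification of spectrograms
#'
#' Runs a pairwise or one-vs-all classification task with the same
#' cross-validation protocol as the discriminant analysis (random 10% test
#' draws, adjacent-echo exclusion). Accuracy per repeat is
#' `100 * (1 - (FP + FN) / Ntest)`. Chance is 50% for the balanced pairwise
#' task; for one-vs-all the majority-class baseline (66.7% for three balanced
#' species) is used. With `smoothed = TRUE` the test echoes of every repeat
#' are scored with the Gaussian-smoothed decision echo and the original
#' offset.
#'
#' @param spectroSet An [EchoSpectrogramSet-class].
#' @param task `list(type = "pairwise", classes = c(a, b))` or
#'   `list(type = "one_vs_all", species = a)`.
#' @param nRepeats,testFraction,exclusionHalfwidth Cross-validation
#'   parameters (defaults 10, 0.1, 2).
#' @param C Soft-margin penalty.
#' @param smoothed Score with the smoothed decision echo.
#' @param seed Seed for the test-set draws.
#' @return A [ClassificationResult-class].
#' @export
runSvmTask <- function(spectroSet, task, nRepeats = 10, testFraction = 0.1,
                       exclusionHalfwidth = 2, C = 1, smoothed = FALSE,
                       seed = 1) {
  stopifnot(is(spectroSet, "EchoSpectrogramSet"))
  cd <- SummarizedExperiment::colData(spectroSet)
  tl <- taskLabels(as.character(cd$species), task)
  x <- t(SummarizedExperiment::assay(spectroSet, "spectro"))[tl$keep, , drop = FALSE]
  meta <- as.data.frame(cd[tl$keep, c("individual", "angleIndex")])
  labels <- tl$labels
  nAngles <- S4Vectors::metadata(spectroSet)$nAngles %||%
    (max(meta$angleIndex) + 1L)
  splits <- makeCvSplits(meta, nAngles, nRepeats, testFraction,
                         exclusionHalfwidth, seed)
  acc <- vapply(splits, function(sp) {
    trainLab <- labels[sp$train]
    if (length(unique(trainLab)) < 2L)
      stop("adjacent-echo exclusion left a single-class training set")
    model <- trainLinearSvm(x[sp$train, , drop = FALSE], trainLab, C = C,
                            positive = tl$positive, taskType = task$type)
    if (smoothed)
      model <- modelWithWeights(model, smoothDecisionEcho(decisionEcho(model)))
    pred <- classifySpectrograms(model, x[sp$test, , drop = FALSE])
    100 * mean(pred == labels[sp$test])
  }, numeric(1L))
  classResult(paste0(tl$name, if (smoothed) " (smoothed)" else ""),
              acc, tl$chance)
}

#' Train one task's model on the full spectrogram set
#'
#' Convenience used by the validation procedures: fits the linear model on
#' all echoes of the task (no held-out set).
#'
#' @inheritParams runSvmTask
#' @return A [LinearDecisionModel-class].
#' @export
trainFullModel <- function(spectroSet, task, C = 1) {
  cd <- SummarizedExperiment::colData(spectroSet)
  tl <- taskLabels(as.character(cd$species), task)
  x <- t(SummarizedExperiment::assay(spectroSet, "spectro"))[tl$keep, , drop = FALSE]
  trainLinearSvm(x, tl$labels, C = C, positive = tl$positive,
                 taskType = task$type)
}

#' @describeIn LinearDecisionModel-class Compact display.
#' @param object A `LinearDecisionModel`.
#' @export
setMethod("show", "LinearDecisionModel", function(object) {
  cat(sprintf(
    "LinearDecisionModel (%s): %s vs %s\n  |w| = %.3g, offset = %.3g, C = %g\n",
    object@taskType, object@positive, object@negative,
    sqrt(sum(object@w^2)), object@offset, object@cost))
})

#' @describeIn DecisionEcho-class Compact display.
#' @param object A `DecisionEcho`.
#' @export
setMethod("show", "DecisionEcho", function(object) {
  cat(sprintf(
    "DecisionEcho: 10 x 93 weights (%s), offset %.3g, |w| range [%.3g, %.3g]\n",
    if (object@smoothed)
      sprintf("smoothed, %dx%d kernel sigma=%g", object@kernelSize,
              object@kernelSize, object@kernelSigma)
    else "raw",
    object@offset, min(object@weights), max(object@weights)))
})
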