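#' Add intensity-like Gaussian noise to a spectrogram
#'
#' Adds Gaussian noise with mean `level` (a fraction of the spectrogram
#' maximum, which is 1 after normalization) and standard deviation `level/2`
#' independently to every pixel. The SD of half the mean keeps the
#' perturbation predominantly positive, emulating added acoustic intensity.
#' The output is deliberately NOT re-normalized: the trained decision rule is
#' tested exactly as learned.
#'
#' @param x Flattened spectrogram vector, matrix (one row per echo), or
#'   10 x 93 matrix.
#' @param level Noise mean as a fraction of the spectrogram maximum, in
#'   `[0, 1]`.
#' @param seed Seed for the noise draw.
#' @param sdFactor SD as a fraction of the mean (default 0.5).
#' @return Object of the same shape with noise added.
#' @export
addSpectrogramNoise <- function(x, level, seed = 1, sdFactor = 0.5) {
  if (!is.numeric(level) || level < 0) stop("noise level must be non-negative")
  if (level > 1) stop("noise level is a fraction of the maximum; expected <= 1")
  if (level == 0) return(x)
  noise <- withSeed(seed, stats::rnorm(length(x), mean = level,
                                       sd = sdFactor * level))
  x + if (is.matrix(x)) matrix(noise, nrow(x), ncol(x)) else noise
}

#' Noise sensitivity of clean-trained one-vs-all classifiers
#'
#' For each species' one-vs-all task and each noise level: classifiers are
#' trained on the original (noiseless) training spectrograms of every
#' cross-validation repeat and scored on test spectrograms with Gaussian
#' noise added. Level 0 reproduces the clean result exactly. Output mirrors
#' the noise-table layout: one row per (species, level) with mean and SD over
#' repeats.
#'
#' @param spectroSet An [EchoSpectrogramSet-class].
#' @param species Species for the one-vs-all tasks (default all in the set).
#' @param levels Noise means as fractions of the spectrogram maximum
#'   (default 0.1..0.5).
#' @param nRepeats,testFraction,exclusionHalfwidth,C As in [runSvmTask()].
#' @param seed Seed for splits and noise.
#' @return data.frame with columns species, level, mean, sd, chance.
#' @export
noiseSensitivity <- function(spectroSet, species = NULL,
                             levels = c(0.1, 0.2, 0.3, 0.4, 0.5),
                             nRepeats = 10, testFraction = 0.1,
                             exclusionHalfwidth = 2, C = 1, seed = 1) {
  stopifnot(is(spectroSet, "EchoSpectrogramSet"))
  cd <- SummarizedExperiment::colData(spectroSet)
  allSpecies <- as.character(cd$species)
  if (is.null(species)) species <- sort(unique(allSpecies))
  xAll <- t(SummarizedExperiment::assay(spectroSet, "spectro"))
  meta <- as.data.frame(cd[, c("individual", "angleIndex")])
  nAngles <- S4Vectors::metadata(spectroSet)$nAngles %||%
    (max(meta$angleIndex) + 1L)
  splits <- makeCvSplits(meta, nAngles, nRepeats, testFraction,
                         exclusionHalfwidth, seed)
  rows <- list()
  for (sp in species) {
    task <- list(type = "one_vs_all", species = sp)
    tl <- taskLabels(allSpecies, task)
    acc <- matrix(NA_real_, nRepeats, length(levels))
    for (r in seq_len(nRepeats)) {
      spl <- splits[[r]]
      model <- trainLinearSvm(xAll[spl$train, , drop = FALSE],
                              tl$labels[spl$train], C = C,
                              positive = tl$positive, taskType = "one_vs_all")
      xt <- xAll[spl$test, , drop = FALSE]
      truth <- tl$labels[spl$test]
      for (li in seq_along(levels)) {
        xn <- addSpectrogramNoise(xt, levels[li],
                                  seed = seed + 7919L * r + 131L * li)
        acc[r, li] <- 100 * mean(classifySpectrograms(model, xn) == truth)
      }
    }
    rows[[sp]] <- data.frame(species = sp, level = levels,
                             mean = colMeans(acc),
                             sd = apply(acc, 2, stats::sd),
                             chance = tl$chance)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Eigen-fish basis of one species' spectrograms
#'
#' Principal decomposition of the mean-centered flattened spectrograms of one
#' species: the species mean vector, the first `k` orthonormal eigen-vectors
#' ("eigen-fishes"), and the SDs of the training projections on each
#' component. `k = 6` reflects the design of three individuals times two
#' aspect sectors per species.
#'
#' @param spectroSet An [EchoSpectrogramSet-class] (optionally already
#'   subset), or a matrix with one flattened spectrogram per row.
#' @param species Species to subset when `spectroSet` carries metadata.
#' @param k Number of components to keep (default 6).
#' @return An [EigenFishBasis-class].
#' @export
eigenfishBasis <- function(spectroSet, species = NULL, k = 6L) {
  if (is(spectroSet, "EchoSpectrogramSet")) {
    cd <- SummarizedExperiment::colData(spectroSet)
    keep <- if (is.null(species)) seq_len(ncol(spectroSet))
            else which(as.character(cd$species) == species)
    x <- t(SummarizedExperiment::assay(spectroSet, "spectro"))[keep, , drop = FALSE]
  } else {
    x <- as.matrix(spectroSet)
  }
  if (nrow(x) < k + 1L)
    stop("need at least k + 1 spectrograms to keep k components")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  new("EigenFishBasis",
      species = species %||% "unspecified",
      center = as.numeric(pca$center),
      vectors = pca$rotation[, seq_len(k), drop = FALSE],
      sds = pca$sdev[seq_len(k)])
}

#' Generate synthetic spectrograms from an eigen-fish basis
#'
#' Each synthetic spectrogram is the species mean plus a linear combination
#' of the k eigen-fishes with weights drawn from zero-mean Gaussians of SD
#' `widthFactor` times the training projection SDs — a distribution much
#' wider than the original echoes for the default `widthFactor = 3`. The
#' default count per species makes the three-species total about five times
#' the data dimensionality (5 x 930 / 3 = 1550).
#'
#' @param basis An [EigenFishBasis-class].
#' @param nPerSpecies Number of synthetic spectrograms (default 1550).
#' @param widthFactor Multiplier on the projection SDs (default 3;
#'   `0` collapses every sample onto the species mean).
#' @param seed Seed for the weight draws.
#' @return Numeric matrix `nPerSpecies x 930` with attribute `"species"`.
#' @export
resampleEigenfish <- function(basis, nPerSpecies = 1550L, widthFactor = 3,
                              seed = 1) {
  stopifnot(is(basis, "EigenFishBasis"))
  if (!is.numeric(widthFactor) || widthFactor < 0)
    stop("widthFactor must be non-negative")
  k <- ncol(basis@vectors)
  W <- withSeed(seed, {
    vapply(seq_len(k), function(j)
      stats::rnorm(nPerSpecies, 0, widthFactor * basis@sds[j]),
      numeric(nPerSpecies))
  })
  if (nPerSpecies == 1L) W <- matrix(W, nrow = 1L)
  out <- matrix(basis@center, nrow = nPerSpecies, ncol = length(basis@center),
                byrow = TRUE) + W %*% t(basis@vectors)
  attr(out, "species") <- basis@species
  out
}

#' Score clean-trained classifiers on eigen-fish resampled data
#'
#' The final validation: one-vs-all models trained on the complete original
#' spectrogram set are scored on synthetic spectrograms resampled from the
#' per-species eigen-fish bases, over `nSeeds` independent generation seeds.
#' High accuracy on this much larger, much more variable synthetic set
#' indicates the classifiers learned a general rule rather than a
#' small-sample artifact.
#'
#' @param spectroSet An [EchoSpectrogramSet-class].
#' @param species Species for the one-vs-all tasks (default all).
#' @param nSeeds Number of generation seeds (default 10).
#' @param nPerSpecies,widthFactor,k Passed to the basis/resampler.
#' @param C Soft-margin penalty for the full-data models.
#' @param seed Base seed.
#' @return data.frame with columns species, level (`"PCA"`), mean, sd,
#'   chance.
#' @export
pcaValidation <- function(spectroSet, species = NULL, nSeeds = 10,
                          nPerSpecies = 1550L, widthFactor = 3, k = 6L,
                          C = 1, seed = 1) {
  stopifnot(is(spectroSet, "EchoSpectrogramSet"))
  cd <- SummarizedExperiment::colData(spectroSet)
  allSpecies <- sort(unique(as.character(cd$species)))
  if (is.null(species)) species <- allSpecies
  bases <- lapply(allSpecies, function(s) eigenfishBasis(spectroSet, s, k))
  names(bases) <- allSpecies
  models <- lapply(species, function(s)
    trainFullModel(spectroSet, list(type = "one_vs_all", species = s), C = C))
  names(models) <- species
  rows <- list()
  for (sp in species) {
    acc <- vapply(seq_len(nSeeds), function(g) {
      xs <- lapply(allSpecies, function(s)
        resampleEigenfish(bases[[s]], nPerSpecies, widthFactor,
                          seed = seed + 104729L * g + match(s, allSpecies)))
      x <- do.call(rbind, xs)
      truth <- rep(allSpecies, each = nPerSpecies)
      truth <- ifelse(truth == sp, sp, "rest")
      100 * mean(classifySpectrograms(models[[sp]], x) == truth)
    }, numeric(1L))
    prop <- 1 / length(allSpecies)
    rows[[sp]] <- data.frame(species = sp, level = "PCA", mean = mean(acc),
                             sd = stats::sd(acc),
                             chance = 100 * max(prop, 1 - prop))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn EigenFishBasis-class Compact display.
#' @param object An `EigenFishBasis`.
#' @export
setMethod("show", "EigenFishBasis", function(object) {
  cat(sprintf(
    "EigenFishBasis: %s, %d components, projection SDs %s\n",
    object@species, ncol(object@vectors),
    paste(signif(object@sds, 3), collapse = ", ")))
})
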