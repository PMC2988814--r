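# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small but complete rotation dataset: 3 species x 2 individuals x 24 angles.
tinyEchoSet <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- generateEchoSet(nIndividuals = 2, angularStep = 15,
                                      masterSeed = 11)
  .fixtures$tiny
}

tinySpectroSet <- function() {
  if (is.null(.fixtures$tinySpectro))
    .fixtures$tinySpectro <- computeSpectrograms(tinyEchoSet())
  .fixtures$tinySpectro
}

# Spectrogram-set fixture built directly from synthetic 930-vectors, with the
# metadata the CV machinery needs. `signal` maps species index to a mean
# feature vector; rows are perturbed by N(0, noiseSd).
syntheticSpectroSet <- function(speciesMeans, nPerSpecies = 60,
                                nAngles = NULL, noiseSd = 0.05, seed = 42) {
  species <- names(speciesMeans)
  if (is.null(nAngles)) nAngles <- nPerSpecies
  set.seed(seed)
  mats <- list(); sp <- c(); ind <- c(); ai <- c()
  for (s in species) {
    m <- matrix(rep(speciesMeans[[s]], each = nPerSpecies), nPerSpecies, 930)
    m <- m + matrix(rnorm(length(m), 0, noiseSd), nrow(m), ncol(m))
    mats[[s]] <- m
    sp <- c(sp, rep(s, nPerSpecies))
    ind <- c(ind, rep(paste0(s, ".1"), nPerSpecies))
    ai <- c(ai, seq_len(nPerSpecies) - 1L)
  }
  x <- do.call(rbind, mats)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectro = t(x)),
    colData = S4Vectors::DataFrame(species = sp, individual = ind,
                                   angle = (ai %% nAngles) * (360 / nAngles),
                                   angleIndex = ai %% nAngles,
                                   aspect = assignAspect((ai %% nAngles) * (360 / nAngles))),
    metadata = list(nAngles = nAngles))
  methods::new("EchoSpectrogramSet", se)
}

# Brute-force soft-margin linear separator: directly minimizes
# 0.5*||w||^2 + C * sum(hinge) over (w, b) by multi-start Nelder-Mead.
# Independent of the libsvm-based training path.
bruteForceSvm <- function(x, y, C = 1, nStarts = 30, seed = 99) {
  y <- ifelse(y == sort(unique(y))[1L], 1, -1)
  obj <- function(p) {
    w <- p[-length(p)]; b <- p[length(p)]
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(x %*% w) + b)))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nStarts)) {
    p0 <- rnorm(ncol(x) + 1L, 0, if (i == 1) 1e-3 else 2)
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(w = best$par[-length(best$par)], b = best$par[length(best$par)],
       value = best$value, positive = sort(unique(y))[1L])
}

softMarginObjective <- function(w, b, x, y, C = 1) {
  y <- ifelse(y == sort(unique(y))[1L], 1, -1)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(x %*% w) + b)))
}
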