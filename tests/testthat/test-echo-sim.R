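test_that("aspect sectors follow the 45-degree convention and partition evenly", {
  expect_identical(assignAspect(0), "tail")
  expect_identical(assignAspect(180), "tail")
  expect_identical(assignAspect(90), "broadside")
  expect_identical(assignAspect(270), "broadside")
  expect_identical(assignAspect(45), "tail")      # boundary inclusive
  expect_identical(assignAspect(45.1), "broadside")
  expect_error(assignAspect(360), "\\[0, 360\\)")
  expect_error(assignAspect(-1), "\\[0, 360\\)")
  # each sector covers 180 degrees of angle measure (grid offset to avoid
  # the boundary angles, which the convention assigns to tail)
  grid <- seq(1.25, 358.75, by = 2.5)
  expect_equal(sum(assignAspect(grid) == "tail"), length(grid) / 2)
})

test_that("a single noiseless reflector places the filtered click at its delay", {
  em <- makeClick("dolphin")
  model <- methods::new("SpeciesModel", name = "one",
    reflectors = list(list(baseDelay = 200e-6, delayAspectAmp = 0,
                           delayPhase = 0, baseGain = 1, gainLobe = 0,
                           gainPhase = 0, filterCenter = 120e3,
                           filterBandwidth = 40e3)),
    individualJitter = c(delay = 0, gain = 0, center = 0),
    bodyLengthRange = c(10, 10))
  echo <- synthesizeEcho(model, 1, 0, em, noiseRms = 0, seed = 1)
  expect_length(echo, 1024L)
  expect_true(all(echo[1:200] == 0))
  expect_gt(max(abs(echo[201:1024])), 0)
  # onset of the response sits exactly at sample 200 (0-based delay)
  expect_equal(min(which(echo != 0)), 201L)
})

test_that("two well-separated reflectors give two envelope maxima", {
  em <- makeClick("dolphin")  # 70 us support
  refl <- function(delay) list(baseDelay = delay, delayAspectAmp = 0,
                               delayPhase = 0, baseGain = 1, gainLobe = 0,
                               gainPhase = 0, filterCenter = 120e3,
                               filterBandwidth = 40e3)
  model <- methods::new("SpeciesModel", name = "two",
    reflectors = list(refl(150e-6), refl(450e-6)),
    individualJitter = c(delay = 0, gain = 0, center = 0),
    bodyLengthRange = c(10, 10))
  echo <- synthesizeEcho(model, 1, 0, em, noiseRms = 0, seed = 1)
  env <- echoEnvelope(echo)
  above <- env > max(env) / 2
  # count contiguous runs of above-half-peak samples
  runs <- rle(above)
  expect_equal(sum(runs$values), 2L)
})

test_that("echo synthesis is bit-reproducible from its seeds", {
  em <- makeClick("dolphin")
  model <- speciesPreset("cod")
  a <- synthesizeEcho(model, 5, 120, em, seed = 9)
  b <- synthesizeEcho(model, 5, 120, em, seed = 9)
  expect_identical(a, b)
  c <- synthesizeEcho(model, 5, 120, em, seed = 10)
  expect_false(identical(a, c))
})

test_that("out-of-window delays are rejected", {
  em <- makeClick("porpoise")  # 270 samples
  model <- methods::new("SpeciesModel", name = "late",
    reflectors = list(list(baseDelay = 900e-6, delayAspectAmp = 0,
                           delayPhase = 0, baseGain = 1, gainLobe = 0,
                           gainPhase = 0, filterCenter = 100e3,
                           filterBandwidth = 30e3)),
    individualJitter = c(delay = 0, gain = 0, center = 0),
    bodyLengthRange = c(10, 10))
  expect_error(synthesizeEcho(model, 1, 0, em, seed = 1), "window")
})

test_that("the default dataset has the study geometry", {
  es <- tinyEchoSet()
  cd <- SummarizedExperiment::colData(es)
  # 3 species x 2 individuals x 24 angles for the shared small fixture
  expect_equal(ncol(es), 3 * 2 * 24)
  expect_equal(nrow(es), 1024L)
  # full-size arithmetic without generating: angle grid from the generator
  expect_equal(length(seq(0, 360 - 2.5, by = 2.5)), 144L)
  expect_setequal(unique(cd$species), c("cod", "mullet", "bass"))
  # angles per individual form an arithmetic grid with the requested spacing
  for (ind in unique(cd$individual)) {
    a <- sort(cd$angle[cd$individual == ind])
    expect_equal(unique(diff(a)), 15)
  }
  expect_true(all(cd$aspect == assignAspect(cd$angle)))
})

test_that("dataset generation is deterministic in the master seed", {
  a <- generateEchoSet(nIndividuals = 1, angularStep = 60, masterSeed = 3)
  b <- generateEchoSet(nIndividuals = 1, angularStep = 60, masterSeed = 3)
  expect_identical(SummarizedExperiment::assay(a, "waveform"),
                   SummarizedExperiment::assay(b, "waveform"))
  c <- generateEchoSet(nIndividuals = 1, angularStep = 60, masterSeed = 4)
  expect_false(identical(SummarizedExperiment::assay(a, "waveform"),
                         SummarizedExperiment::assay(c, "waveform")))
})

test_that("generateEchoSet agrees with the per-echo reference path", {
  # the batched generator must reproduce synthesizeEcho exactly, noise included
  es <- generateEchoSet(nIndividuals = 1, angularStep = 90, masterSeed = 5)
  cd <- SummarizedExperiment::colData(es)
  wf <- SummarizedExperiment::assay(es, "waveform")
  em <- makeClick("dolphin")
  j <- which(cd$species == "mullet" & cd$angle == 90)
  iseed <- (5L %% 100000L) + 1009L * 2L + 101L * 1L
  ref <- synthesizeEcho(speciesPreset("mullet"), iseed, 90, em,
                        noiseRms = 0.05, seed = cd$pingSeed[j])
  expect_identical(wf[, j], ref)
})

test_that("fewer than two species is rejected", {
  expect_error(generateEchoSet(species = "cod"), "2 species")
  expect_error(generateEchoSet(angularStep = 7), "integer multiple")
})

test_that("neighbouring angles are more alike than distant ones", {
  es <- tinyEchoSet()
  wf <- SummarizedExperiment::assay(es, "waveform")
  cd <- SummarizedExperiment::colData(es)
  lagCor <- function(lag) {
    out <- c()
    for (ind in unique(cd$individual)) {
      j <- which(cd$individual == ind)
      env <- apply(wf[, j], 2, echoEnvelope)
      n <- ncol(env)
      for (a in seq_len(n))
        out <- c(out, cor(env[, a], env[, (a + lag - 1) %% n + 1]))
    }
    mean(out)
  }
  expect_gt(lagCor(1), lagCor(6))  # 15 deg apart vs 90 deg apart
})

test_that("huge anatomical jitter erodes cross-individual species structure", {
  # with unbounded jitter the species presets lose their shared anatomy, so a
  # model trained on one individual per species stops generalizing to unseen
  # individuals (within-individual splits can stay separable regardless)
  blur <- lapply(c("cod", "mullet", "bass"), function(s) {
    m <- speciesPreset(s)
    m@individualJitter <- c(delay = 0.3, gain = 1.0, center = 0.6)
    m
  })
  names(blur) <- c("cod", "mullet", "bass")
  esBlur <- generateEchoSet(blur, nIndividuals = 2, angularStep = 15,
                            masterSeed = 11)
  crossIndivAcc <- function(es) {
    ft <- as.data.frame(featureTable(es))
    train <- grepl("\\.1$", ft$individual)
    x <- as.matrix(ft[, c("m2", "m3n", "m4n", "crest", "A", "b")])
    model <- fitQda(x[train, ], ft$species[train])
    mean(predictQda(model, x[!train, ]) == ft$species[!train])
  }
  expect_gt(crossIndivAcc(tinyEchoSet()), crossIndivAcc(esBlur))
  expect_gt(crossIndivAcc(tinyEchoSet()), 1 / 3)
})
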