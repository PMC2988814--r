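test_that("the max-margin separator of a two-point problem is recovered", {
  x <- rbind(c(-1, 0), c(1, 0), c(-1, 0.1), c(1, -0.1))
  y <- c("A", "B", "A", "B")
  m <- trainLinearSvm(x, y, C = 1, positive = "B")
  # geometry: w proportional to (1, 0), offset ~ 0, unit margins
  expect_gt(m@w[1], 0)
  expect_lt(abs(m@w[2] / m@w[1]), 0.05)
  expect_lt(abs(m@offset), 0.05)
  d <- drop(x %*% m@w) + m@offset
  expect_equal(abs(d), rep(1, 4), tolerance = 0.05)
  expect_identical(classifySpectrograms(m, x), y)
})

test_that("relabeling the classes flips the separator but not the predictions", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c("A", "B"), each = 20)
  m1 <- trainLinearSvm(x, y, positive = "A")
  m2 <- trainLinearSvm(x, y, positive = "B")
  expect_equal(m1@w, -m2@w, tolerance = 1e-6)
  expect_equal(m1@offset, -m2@offset, tolerance = 1e-6)
  expect_identical(classifySpectrograms(m1, x), classifySpectrograms(m2, x))
})

test_that("duplicating every training point leaves the separator unchanged", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30, -2), 15, 2), matrix(rnorm(30, 2), 15, 2))
  y <- rep(c("A", "B"), each = 15)
  m1 <- trainLinearSvm(x, y)
  m2 <- trainLinearSvm(rbind(x, x), c(y, y))
  expect_equal(m1@w, m2@w, tolerance = 1e-4)
  expect_equal(m1@offset, m2@offset, tolerance = 1e-4)
})

test_that("single-class input and geometry mismatches are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(trainLinearSvm(x, rep("A", 10)), "two classes")
  m <- trainLinearSvm(x, rep(c("A", "B"), 5))
  expect_error(classifySpectrograms(m, matrix(0, 2, 5)), "geometry")
})

test_that("the decision rule is exactly the sign of the inner product", {
  w <- rnorm(930)
  m <- methods::new("LinearDecisionModel", w = w, offset = 0, cost = 1,
                    taskType = "pairwise", positive = "P", negative = "N")
  expect_identical(classifySpectrograms(m, w / sum(w^2)), "P")
  ortho <- rnorm(930)
  ortho <- ortho - w * sum(ortho * w) / sum(w^2)
  m2 <- methods::new("LinearDecisionModel", w = w, offset = -0.5, cost = 1,
                     taskType = "pairwise", positive = "P", negative = "N")
  expect_identical(classifySpectrograms(m2, ortho), "N")
  # an exact zero goes to the positive class
  m3 <- methods::new("LinearDecisionModel", w = w, offset = 0, cost = 1,
                     taskType = "pairwise", positive = "P", negative = "N")
  expect_identical(classifySpectrograms(m3, ortho), "P")
})

test_that("training matches brute-force objective minimization on small instances", {
  set.seed(14)
  for (rep in 1:3) {
    n <- sample(8:20, 1)
    x <- matrix(rnorm(2 * n, sd = 1.5), n, 2)
    y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.5) > 0, "a", "b")
    if (length(unique(y)) < 2) next
    m <- trainLinearSvm(x, y, C = 1, positive = "a")
    bf <- bruteForceSvm(x, y, C = 1)
    oTrained <- softMarginObjective(m@w, m@offset, x, y, C = 1)
    oBrute <- softMarginObjective(bf$w, bf$b, x, y, C = 1)
    # equal optima (the dual solver cannot beat the direct minimizer and the
    # direct minimizer must reach the dual optimum)
    expect_equal(oTrained, oBrute, tolerance = 1e-3)
    predBrute <- ifelse(drop(x %*% bf$w) + bf$b >= 0, "a", "b")
    agree <- mean(predBrute == classifySpectrograms(m, x))
    expect_gte(agree, 0.9)
  }
})

test_that("the smoothing kernel is unit-sum and the smoother preserves structure", {
  k <- gaussianKernel2d(10, 7)
  expect_equal(dim(k), c(10L, 10L))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  m <- methods::new("LinearDecisionModel", w = rnorm(930), offset = 0.3,
                    cost = 1, taskType = "pairwise",
                    positive = "P", negative = "N")
  de <- decisionEcho(m)
  expect_false(de@smoothed)
  expect_identical(flattenSpectrogram(de@weights), m@w)
  sm <- smoothDecisionEcho(de)
  expect_true(sm@smoothed)
  expect_identical(sm@offset, de@offset)
  expect_error(smoothDecisionEcho(sm), "already smoothed")
  # constants are fixed points (reflection border + unit-sum kernel)
  deConst <- methods::new("DecisionEcho", weights = matrix(2.5, 10, 93),
                          offset = 0, smoothed = FALSE, kernelSize = 10L,
                          kernelSigma = 7, freqAxis = de@freqAxis,
                          timeAxis = de@timeAxis)
  smConst <- smoothDecisionEcho(deConst)
  expect_equal(smConst@weights, deConst@weights, tolerance = 1e-12)
  # an impulse spreads: peak strictly reduced, mass approximately kept (the
  # 10-row matrix is narrower than the kernel, so some row mass reflects out)
  imp <- matrix(0, 10, 93); imp[5, 46] <- 1
  deImp <- methods::new("DecisionEcho", weights = imp, offset = 0,
                        smoothed = FALSE, kernelSize = 10L, kernelSigma = 7,
                        freqAxis = de@freqAxis, timeAxis = de@timeAxis)
  smImp <- smoothDecisionEcho(deImp)
  expect_lt(max(smImp@weights), 1)
  expect_equal(sum(smImp@weights), 1, tolerance = 0.1)
  # oracle: direct double-loop convolution with reflected indices
  reflectIdx <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  oracle <- matrix(0, 10, 93)
  for (r in 1:10) for (cc in 1:93) {
    acc <- 0
    for (i in 1:10) for (j in 1:10)
      acc <- acc + k[i, j] * imp[reflectIdx(r + i - 5, 10),
                                 reflectIdx(cc + j - 5, 93)]
    oracle[r, cc] <- acc
  }
  expect_equal(smImp@weights, oracle, tolerance = 1e-12)
})

test_that("an informative frequency row dominates the decision echo", {
  base <- rep(0, 930)
  rowIdx <- function(r) ((r - 1) * 93 + 1):(r * 93)
  meanA <- base; meanA[rowIdx(5)] <- 1
  meanB <- base; meanB[rowIdx(5)] <- -1
  sp <- syntheticSpectroSet(list(a = meanA, b = meanB), nPerSpecies = 30,
                            noiseSd = 0.2)
  m <- trainFullModel(sp, list(type = "pairwise", classes = c("a", "b")))
  de <- decisionEcho(m)
  rowEnergy <- rowMeans(abs(de@weights))
  expect_equal(which.max(rowEnergy), 5L)
})

test_that("separable spectrogram fixtures reach ceiling and shuffled labels fall to chance", {
  set.seed(15)
  meanA <- rnorm(930); meanB <- rnorm(930)
  sp <- syntheticSpectroSet(list(a = meanA, b = meanB), nPerSpecies = 50,
                            noiseSd = 0.1)
  res <- runSvmTask(sp, list(type = "pairwise", classes = c("a", "b")),
                    nRepeats = 5, seed = 3)
  expect_gte(mean(accuracies(res)), 99)
  expect_equal(res@chance, 50)
  # shuffle labels: performance collapses to the 50% coin-flip level
  cdShuf <- SummarizedExperiment::colData(sp)
  set.seed(16)
  cdShuf$species <- sample(cdShuf$species)
  spShuf <- methods::new("EchoSpectrogramSet",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(spectro = SummarizedExperiment::assay(sp, "spectro")),
      colData = cdShuf,
      metadata = S4Vectors::metadata(sp)))
  resShuf <- runSvmTask(spShuf, list(type = "pairwise", classes = c("a", "b")),
                        nRepeats = 10, seed = 3)
  # within 3 SD of chance at ~10 test echoes per repeat over 10 repeats
  expect_lt(abs(mean(accuracies(resShuf)) - 50), 3 * 50 / sqrt(10 * 10))
})

test_that("smoothing barely hurts a broad-blob decision rule", {
  base <- rep(0, 930)
  blob <- as.vector(t(outer(exp(-((1:10) - 5)^2 / 8),
                            exp(-((1:93) - 46)^2 / 800))))
  sp <- syntheticSpectroSet(list(a = blob, b = -blob), nPerSpecies = 40,
                            noiseSd = 0.3)
  raw <- runSvmTask(sp, list(type = "pairwise", classes = c("a", "b")),
                    nRepeats = 5, seed = 4)
  sm <- runSvmTask(sp, list(type = "pairwise", classes = c("a", "b")),
                   nRepeats = 5, smoothed = TRUE, seed = 4)
  expect_lt(abs(mean(accuracies(raw)) - mean(accuracies(sm))), 5)
})

test_that("task runs are deterministic in their seed", {
  sp <- tinySpectroSet()
  a <- runSvmTask(sp, list(type = "one_vs_all", species = "cod"),
                  nRepeats = 3, seed = 6)
  b <- runSvmTask(sp, list(type = "one_vs_all", species = "cod"),
                  nRepeats = 3, seed = 6)
  expect_identical(accuracies(a), accuracies(b))
  expect_equal(a@chance, 100 * 2 / 3, tolerance = 1e-9)
})
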