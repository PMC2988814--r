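test_that("well-separated Gaussian classes are learned almost perfectly", {
  set.seed(1)
  x <- rbind(matrix(rnorm(50 * 6), 50, 6),
             matrix(rnorm(50 * 6, mean = 10), 50, 6))
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c("a", "b"), each = 50)
  model <- fitQda(x, y)
  expect_gte(mean(predictQda(model, x) == y), 0.99)
})

test_that("identically distributed classes score near 50% held out", {
  set.seed(2)
  x <- matrix(rnorm(400 * 6), 400, 6)
  y <- rep(c("a", "b"), each = 200)
  model <- fitQda(x[c(1:150, 201:350), ], y[c(1:150, 201:350)])
  held <- c(151:200, 351:400)
  acc <- mean(predictQda(model, x[held, ]) == y[held])
  # 3 binomial SDs around 0.5 at n = 100
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("duplicating every training sample leaves predictions unchanged", {
  set.seed(3)
  x <- matrix(rnorm(60 * 6), 60, 6)
  y <- rep(c("a", "b", "c"), each = 20)
  xt <- matrix(rnorm(30 * 6), 30, 6)
  m1 <- fitQda(x, y)
  m2 <- fitQda(rbind(x, x), c(y, y))
  expect_identical(predictQda(m1, xt), predictQda(m2, xt))
})

test_that("quadratic scores match an independent closed-form evaluation", {
  set.seed(4)
  x <- matrix(rnorm(80 * 3), 80, 3)
  x[41:80, ] <- x[41:80, ] + 1.5
  y <- rep(c("a", "b"), each = 40)
  model <- fitQda(x, y, ridge = 0)
  xt <- matrix(rnorm(20 * 3), 20, 3)
  # closed-form Gaussian discriminant with population covariances
  ref <- sapply(c("a", "b"), function(k) {
    xk <- x[y == k, ]
    mu <- colMeans(xk)
    S <- crossprod(sweep(xk, 2, mu)) / nrow(xk)
    apply(xt, 1, function(v)
      -0.5 * determinant(S)$modulus[1] -
        0.5 * drop(t(v - mu) %*% solve(S) %*% (v - mu)) + log(0.5))
  })
  expect_identical(predictQda(model, xt),
                   c("a", "b")[max.col(ref, ties.method = "first")])
})

test_that("predictions agree with an established QDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- matrix(rnorm(300 * 4), 300, 4)
  x[101:200, ] <- x[101:200, ] * 2 + 1
  x[201:300, ] <- sweep(x[201:300, ], 2, c(3, -1, 0, 2), "+")
  y <- rep(c("a", "b", "c"), each = 100)
  ours <- predictQda(fitQda(x, y, ridge = 0), x)
  ref <- as.character(predict(MASS::qda(x, grouping = factor(y)), x)$class)
  # conventions differ only by an n/(n-1) covariance factor: near-total overlap
  expect_gt(mean(ours == ref), 0.99)
})

test_that("classes with fewer than two samples are rejected", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(fitQda(x, c("a", "a", "a", "b")), "at least 2")
})

test_that("the t-test against chance matches the closed form", {
  acc <- c(60, 62, 58, 61, 59, 60, 63, 57, 60, 61)
  got <- testVsChance(acc, 33)
  tstat <- (mean(acc) - 33) / (sd(acc) / sqrt(length(acc)))
  expect_equal(got$p, pt(tstat, df = 9, lower.tail = FALSE), tolerance = 1e-8)
  expect_lt(got$p, 1e-6)
  expect_false(got$degenerate)
  # below-chance accuracies give p > 0.5 (one-sided)
  expect_gt(testVsChance(c(20, 22, 19, 21), 33)$p, 0.5)
  # zero-variance cases fall back to exact comparison with a flag
  atChance <- testVsChance(rep(33.3, 5), 33.3)
  expect_equal(atChance$p, 0.5)
  expect_true(atChance$degenerate)
  expect_equal(testVsChance(rep(90, 5), 33)$p, 0)
  expect_equal(testVsChance(rep(10, 5), 33)$p, 1)
})

test_that("adjacent echoes of tested individuals never enter training", {
  meta <- data.frame(
    individual = rep(c("i1", "i2"), each = 24),
    angleIndex = rep(0:23, 2)
  )
  splits <- makeCvSplits(meta, nAngles = 24, nRepeats = 10,
                         testFraction = 0.1, exclusionHalfwidth = 2, seed = 4)
  for (sp in splits) {
    expect_length(intersect(sp$test, sp$train), 0)
    for (j in sp$test) {
      same <- which(meta$individual == meta$individual[j])
      d <- abs(meta$angleIndex[same] - meta$angleIndex[j])
      d <- pmin(d, 24 - d)
      expect_length(intersect(sp$train, same[d <= 2]), 0)
    }
  }
})

test_that("cross-validation splits are reproducible under a fixed seed", {
  meta <- data.frame(individual = rep("i1", 50), angleIndex = 0:49)
  a <- makeCvSplits(meta, 50, seed = 8)
  b <- makeCvSplits(meta, 50, seed = 8)
  expect_identical(a, b)
})

test_that("perfectly separated feature clusters classify every species", {
  set.seed(6)
  n <- 40
  feats <- data.frame(
    species = rep(c("cod", "mullet", "bass"), each = n),
    individual = rep(c("cod.1", "mullet.1", "bass.1"), each = n),
    angleIndex = rep(0:(n - 1), 3)
  )
  offs <- c(cod = 0, mullet = 50, bass = 100)
  for (f in c("m2", "m3n", "m4n", "crest", "A", "b"))
    feats[[f]] <- rnorm(3 * n, mean = offs[feats$species], sd = 0.5)
  res <- crossvalidateDfa(feats, nAngles = n, nRepeats = 5, seed = 1)
  for (r in res) expect_gte(mean(accuracies(r), na.rm = TRUE), 99)
})

test_that("cross-validated DFA is deterministic in its seed", {
  ft <- featureTable(tinyEchoSet())
  a <- crossvalidateDfa(ft, nRepeats = 3, seed = 5)
  b <- crossvalidateDfa(ft, nRepeats = 3, seed = 5)
  expect_identical(lapply(a, accuracies), lapply(b, accuracies))
})

test_that("ablation of an uninformative feature changes little; of the only informative one, everything", {
  set.seed(9)
  n <- 60
  feats <- data.frame(
    species = rep(c("a", "b"), each = n),
    individual = rep(c("a.1", "b.1"), each = n),
    angleIndex = rep(0:(n - 1), 2),
    good = rnorm(2 * n, mean = rep(c(0, 30), each = n)),
    noise = rnorm(2 * n)
  )
  full <- crossvalidateDfa(feats, featureNames = c("good", "noise"),
                           nAngles = n, chance = 50, nRepeats = 5, seed = 2)
  noNoise <- featureAblation(feats, "noise",
                             featureNames = c("good", "noise"),
                             nAngles = n, chance = 50, nRepeats = 5, seed = 2)
  noGood <- featureAblation(feats, "good",
                            featureNames = c("good", "noise"),
                            nAngles = n, chance = 50, nRepeats = 5, seed = 2)
  fullMean <- mean(sapply(full, function(r) mean(accuracies(r), na.rm = TRUE)))
  fullSd <- mean(sapply(full, function(r) sd(accuracies(r))))
  noNoiseMean <- mean(sapply(noNoise, function(r) mean(accuracies(r), na.rm = TRUE)))
  noGoodMean <- mean(sapply(noGood, function(r) mean(accuracies(r), na.rm = TRUE)))
  expect_lte(abs(noNoiseMean - fullMean), max(fullSd, 1))
  expect_lt(noGoodMean, 70)  # collapses toward the 50% chance level
  expect_error(featureAblation(feats, "nope",
                               featureNames = c("good", "noise")), "unknown")
})
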