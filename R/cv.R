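# Shared cross-validation machinery: random test draws with exclusion of
# echoes angularly adjacent to test echoes of the same individual. Used by
# both the discriminant analysis and the max-margin classifier so the two
# protocols are identical.

#' Cross-validation splits with adjacent-echo exclusion
#'
#' For each repeat a random `testFraction` of the echoes is drawn as the test
#' set; every echo of the same individual within `exclusionHalfwidth` angular
#' positions of a test echo (on the circular rotation grid) is excluded from
#' the training set, so a classifier is never trained on the immediate
#' angular neighbours of an echo it is tested on.
#'
#' @param meta Data-frame-like with columns `individual` and `angleIndex`
#'   (0-based position on the rotation grid).
#' @param nAngles Number of positions on the full rotation grid (for circular
#'   adjacency).
#' @param nRepeats Number of repeats (default 10).
#' @param testFraction Fraction of echoes drawn as test set (default 0.1).
#' @param exclusionHalfwidth Angular positions excluded on each side of a
#'   test echo (default 2).
#' @param seed Seed controlling the draws.
#'
#' @return List of `nRepeats` lists with integer indices `test` and `train`.
#' @export
makeCvSplits <- function(meta, nAngles, nRepeats = 10, testFraction = 0.1,
                         exclusionHalfwidth = 2, seed = 1) {
  n <- nrow(meta)
  indiv <- as.character(meta$individual)
  aidx <- as.integer(meta$angleIndex)
  nTest <- max(1L, round(testFraction * n))
  withSeed(seed, lapply(seq_len(nRepeats), function(r) {
    test <- sort(sample.int(n, nTest))
    drop <- logical(n)
    drop[test] <- TRUE
    for (j in test) {
      same <- which(indiv == indiv[j])
      d <- abs(aidx[same] - aidx[j])
      d <- pmin(d, nAngles - d)
      drop[same[d <= exclusionHalfwidth]] <- TRUE
    }
    list(test = test, train = which(!drop))
  }))
}

# One-sided one-sample t-test of accuracies above chance; exact limits when
# the repeat accuracies have zero variance.
#' @noRd
chanceTest <- function(acc, chance) {
  acc <- acc[!is.na(acc)]
  if (length(acc) < 2L || stats::sd(acc) == 0) {
    m <- mean(acc)
    p <- if (m > chance) 0 else if (m < chance) 1 else 0.5
    return(list(p = p, degenerate = TRUE))
  }
  list(p = stats::t.test(acc, mu = chance, alternative = "greater")$p.value,
       degenerate = FALSE)
}

#' One-sided t-test of cross-validation accuracies against chance
#'
#' One-sample t-test of mean accuracy above the chance level. With fewer than
#' two repeats or zero variance the t statistic is undefined; the exact
#' comparison is then reported (p = 0 if all repeats are above chance, 1 if
#' below, 0.5 if exactly at chance) with a degenerate flag.
#'
#' @param accuracies Percent accuracies, one per repeat.
#' @param chance Chance level in percent.
#' @return List with `p` and logical `degenerate`.
#'
#' @examples
#' testVsChance(c(60, 62, 58, 61, 59), 33)
#' @export
testVsChance <- function(accuracies, chance) {
  chanceTest(accuracies, chance)
}

# Constructor shorthand for ClassificationResult.
#' @noRd
classResult <- function(task, acc, chance) {
  ct <- chanceTest(acc, chance)
  new("ClassificationResult", task = task, accuracies = acc,
      chance = chance, pValue = ct$p, degenerate = ct$degenerate)
}

#' Per-repeat accuracies of a ClassificationResult
#' @param x A [ClassificationResult-class].
#' @return Numeric vector of percent accuracies.
#' @export
accuracies <- function(x) {
  stopifnot(is(x, "ClassificationResult"))
  x@accuracies
}

#' Summarize a ClassificationResult as a one-row data frame
#' @param x A [ClassificationResult-class].
#' @return data.frame with task, mean, sd, chance, p, degenerate.
#' @export
resultRow <- function(x) {
  stopifnot(is(x, "ClassificationResult"))
  data.frame(task = x@task, mean = mean(x@accuracies, na.rm = TRUE),
             sd = stats::sd(x@accuracies[!is.na(x@accuracies)]), chance = x@chance,
             p = x@pValue, degenerate = x@degenerate)
}

#' @describeIn ClassificationResult-class Compact display in the
#'   "mean +- sd" style of the study tables.
#' @param object A `ClassificationResult`.
#' @export
setMethod("show", "ClassificationResult", function(object) {
  star <- if (!is.na(object@pValue) && object@pValue < 0.05) "*" else ""
  cat(sprintf(
    "ClassificationResult: %s\n  %.0f+-%.0f%%%s over %d repeats (chance %.1f%%, one-sided p = %.3g)\n",
    object@task, mean(object@accuracies, na.rm = TRUE),
    stats::sd(object@accuracies[!is.na(object@accuracies)]), star, length(object@accuracies),
    object@chance, object@pValue))
})
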