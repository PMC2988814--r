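#' Hilbert envelope of an echo waveform
#'
#' Magnitude of the analytic signal. The envelope is non-negative and
#' dominates the absolute value of the raw waveform pointwise.
#'
#' @param x Numeric waveform (or an [EmissionSignal-class]).
#' @return Numeric envelope of the same length.
#' @export
echoEnvelope <- function(x) {
  x <- asWaveform(x)
  if (length(x) == 0L) stop("empty waveform")
  analyticEnvelope(x)
}

#' Centralized moment statistics of an envelope
#'
#' Population-normalized (1/N) moments of the envelope samples s_i:
#' the centralized second moment (variance) `m2 = mean((s - mean(s))^2)`, the
#' normalized centralized third moment `m3n = m3 / m2^(3/2)` (skewness), and
#' the normalized centralized fourth moment `m4n = m4 / m2^2` (kurtosis).
#' A constant envelope has `m2 = 0`; the normalized moments are then undefined
#' and the result is flagged degenerate (NA, never silent NaN).
#'
#' @param env Non-negative numeric envelope, length >= 2.
#' @return List with `m2`, `m3n`, `m4n`, and logical `degenerate`.
#'
#' @examples
#' momentStats(c(1, 2, 3, 4, 5))  # m2 = 2, m3n = 0, m4n = 1.7
#' @export
momentStats <- function(env) {
  if (length(env) < 2L) stop("envelope must have at least 2 samples")
  s <- as.numeric(env)
  d <- s - mean(s)
  m2 <- mean(d^2)
  if (m2 <= .Machine$double.eps * max(mean(s)^2, 1))
    return(list(m2 = m2, m3n = NA_real_, m4n = NA_real_, degenerate = TRUE))
  list(m2 = m2, m3n = mean(d^3) / m2^1.5, m4n = mean(d^4) / m2^2,
       degenerate = FALSE)
}

#' Crest factor of an envelope
#'
#' Ratio between the peak amplitude and the root mean square,
#' `max(s) / sqrt(mean(s^2))`. Always >= 1 for a non-negative envelope and
#' invariant to amplitude scaling.
#'
#' @param env Non-negative numeric envelope, not all zero.
#' @return Dimensionless crest factor.
#' @export
crestFactor <- function(env) {
  s <- as.numeric(env)
  if (length(s) == 0L || all(s == 0)) stop("all-zero envelope has no crest factor")
  max(s) / sqrt(mean(s^2))
}

#' Exponential fit to the envelope amplitude distribution
#'
#' Histograms the envelope amplitudes into `nBins` equal-width bins over
#' `[0, max(env)]`, normalizes the counts to a probability distribution P_i,
#' and fits `P_i = A * exp(-b * x_i)` over the bin centers x_i by nonlinear
#' least squares (positivity-constrained b, initialized from a log-linear fit
#' on the occupied bins). Empty bins are kept at 0 and enter the objective.
#'
#' @param env Non-negative numeric envelope with at least 2 distinct values.
#' @param nBins Number of histogram bins (>= 5, default 50).
#' @return List with `A` (amplitude), `b` (width, 1/amplitude units), `rss`
#'   (residual sum of squares) and logical `degenerate` (single occupied bin
#'   or failed fit).
#' @export
expFit <- function(env, nBins = 50L) {
  if (nBins < 5L) stop("nBins must be at least 5")
  s <- as.numeric(env)
  if (length(unique(s)) < 2L || max(s) <= 0)
    return(list(A = NA_real_, b = NA_real_, rss = NA_real_, degenerate = TRUE))
  breaks <- seq(0, max(s), length.out = nBins + 1L)
  # findInterval puts x == max in the last bin; values at 0 in the first.
  bin <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L), nBins)
  counts <- tabulate(bin, nbins = nBins)
  P <- counts / sum(counts)
  x <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  occ <- which(P > 0)
  if (length(occ) < 2L)
    return(list(A = NA_real_, b = NA_real_, rss = NA_real_, degenerate = TRUE))
  # Log-linear initialization on occupied bins.
  lf <- stats::lm(log(P[occ]) ~ x[occ])
  A0 <- exp(unname(stats::coef(lf)[1L]))
  b0 <- max(-unname(stats::coef(lf)[2L]), 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ A * exp(-b * x),
                      data = data.frame(P = P, x = x),
                      start = list(A = A0, b = b0),
                      lower = c(A = 0, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = A0, b = b0, rss = NA_real_, degenerate = TRUE))
  co <- stats::coef(fit)
  list(A = unname(co["A"]), b = unname(co["b"]),
       rss = sum(stats::residuals(fit)^2), degenerate = FALSE)
}

#' Extract the six envelope statistics from one echo
#'
#' Composition of [echoEnvelope()], [momentStats()], [crestFactor()] and
#' [expFit()]: the centralized second moment, normalized third and fourth
#' moments, crest factor, and the amplitude A and width b of the exponential
#' fit to the envelope amplitude distribution.
#'
#' @param x Numeric echo waveform.
#' @param nBins Histogram bins for the exponential fit.
#' @return Named numeric vector `c(m2, m3n, m4n, crest, A, b)` with attribute
#'   `degenerate` (logical).
#' @export
extractFeatures <- function(x, nBins = 50L) {
  env <- echoEnvelope(x)
  mo <- momentStats(env)
  cr <- crestFactor(env)
  ef <- expFit(env, nBins)
  out <- c(m2 = mo$m2, m3n = mo$m3n, m4n = mo$m4n, crest = cr,
           A = ef$A, b = ef$b)
  attr(out, "degenerate") <- mo$degenerate || ef$degenerate
  out
}

#' Envelope feature table for a whole echo set
#'
#' Applies [extractFeatures()] to every echo and returns the per-echo
#' metadata together with the six feature columns and a degenerate flag.
#'
#' @param echoSet An [EchoSet-class].
#' @param nBins Histogram bins for the exponential fit.
#' @return A [S4Vectors::DataFrame] with the `colData` columns of `echoSet`
#'   plus `m2, m3n, m4n, crest, A, b, degenerate`.
#' @export
featureTable <- function(echoSet, nBins = 50L) {
  stopifnot(is(echoSet, "EchoSet"))
  wf <- SummarizedExperiment::assay(echoSet, "waveform")
  feats <- t(vapply(seq_len(ncol(wf)), function(j) {
    f <- extractFeatures(wf[, j], nBins)
    c(f, degenerate = as.numeric(attr(f, "degenerate")))
  }, numeric(7L)))
  out <- SummarizedExperiment::colData(echoSet)
  for (nm in c("m2", "m3n", "m4n", "crest", "A", "b"))
    out[[nm]] <- feats[, nm]
  out$degenerate <- feats[, "degenerate"] > 0
  out
}
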