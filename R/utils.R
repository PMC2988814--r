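# Internal helpers: seeded evaluation and the analytic-signal envelope.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

# Magnitude of the analytic signal (Hilbert envelope) of a real vector.
# Standard single-sided spectrum construction via the FFT.
#' @noRd
analyticEnvelope <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty waveform")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Extract the numeric waveform from an EmissionSignal or a numeric vector.
#' @noRd
asWaveform <- function(x) {
  if (is(x, "EmissionSignal")) x@samples
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected an EmissionSignal or a numeric waveform")
}

# Sample rate associated with x, defaulting to `default` for bare vectors.
#' @noRd
waveformRate <- function(x, default = 1e6) {
  if (is(x, "EmissionSignal")) x@sampleRate else default
}
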