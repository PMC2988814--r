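# Spectrogram geometry constants: 100-point Hann window, 10-sample hop (90%
# overlap), 1024-sample echoes at 1 MHz. Frames are left-aligned and the
# final partial window is dropped: (1024 - 100) / 10 + 1 = 93 frames. The
# transform grid spacing is fs / window = 10 kHz; bins 6..15 (60..150 kHz
# inclusive) are retained: 10 frequency rows.
SPECTRO_WINDOW <- 100L
SPECTRO_HOP <- 10L
SPECTRO_NFRAMES <- 93L
SPECTRO_BINS <- 7:16          # 1-based FFT bin rows for 60..150 kHz
SPECTRO_FREQS <- seq(60e3, 150e3, by = 10e3)
SPECTRO_DB_FLOOR <- 80        # dB below the matrix maximum

#' Compute the band-limited dB spectrogram of one echo
#'
#' Short-time magnitude spectra with a 100-point Hann window and 90% overlap
#' (10 kHz frequency resolution, 0.1 ms time resolution), band-pass limited
#' to 60-150 kHz (the range audible to dolphins and porpoises), converted to
#' a dB scale with a floor 80 dB below the maximum, and affinely rescaled to
#' `[0, 1]` so the maximum is exactly 1. This is the input representation
#' `x` of the linear classifier.
#'
#' @param x Numeric echo waveform of exactly 1024 samples.
#' @param sampleRate Must be 1 MHz.
#' @return An [EchoSpectrogram-class] (10 x 93).
#' @export
computeSpectrogram <- function(x, sampleRate = 1e6) {
  x <- asWaveform(x)
  if (length(x) != 1024L)
    stop("spectrogram input must have exactly 1024 samples")
  if (sampleRate != 1e6)
    stop("spectrogram geometry is defined for a 1 MHz sample rate")
  if (all(x == 0)) stop("silent echo has no normalizable spectrogram")
  win <- 0.5 * (1 - cos(2 * pi * (0:(SPECTRO_WINDOW - 1L)) / (SPECTRO_WINDOW - 1L)))
  starts <- (seq_len(SPECTRO_NFRAMES) - 1L) * SPECTRO_HOP
  frames <- vapply(starts, function(s) x[(s + 1L):(s + SPECTRO_WINDOW)] * win,
                   numeric(SPECTRO_WINDOW))
  mag <- Mod(stats::mvfft(frames))[SPECTRO_BINS, , drop = FALSE]
  mmax <- max(mag)
  db <- 20 * log10(pmax(mag, mmax * 10^(-SPECTRO_DB_FLOOR / 20)))
  rng <- range(db)
  if (rng[2] - rng[1] <= 0)
    stop("degenerate spectrogram: dB matrix is constant")
  m <- (db - rng[1]) / (rng[2] - rng[1])
  dimnames(m) <- list(paste0(SPECTRO_FREQS / 1e3, "kHz"), NULL)
  new("EchoSpectrogram", mat = m, freqAxis = SPECTRO_FREQS,
      timeAxis = (starts + (SPECTRO_WINDOW - 1) / 2) / sampleRate)
}

#' Flatten a spectrogram to the classifier's feature vector
#'
#' Row-major flattening: all 93 frames of the lowest retained frequency row
#' (60 kHz) first, then the next row. [unflattenSpectrogram()] is the exact
#' inverse.
#'
#' @param x An [EchoSpectrogram-class] or a 10 x 93 matrix.
#' @return Numeric vector of length 930.
#' @export
flattenSpectrogram <- function(x) {
  m <- if (is(x, "EchoSpectrogram")) x@mat else x
  if (!is.matrix(m) || !all(dim(m) == c(10L, 93L)))
    stop("expected a 10 x 93 spectrogram")
  as.vector(t(m))
}

#' Reshape a flattened feature vector back to spectrogram geometry
#'
#' @param v Numeric vector of length 930.
#' @return A 10 x 93 matrix.
#' @export
unflattenSpectrogram <- function(v) {
  if (length(v) != 930L) stop("expected a vector of length 930 (10 x 93)")
  t(matrix(v, nrow = 93L, ncol = 10L))
}

#' Spectrograms of a whole echo set
#'
#' Applies [computeSpectrogram()] to every echo and stacks the flattened
#' results into an [EchoSpectrogramSet-class] (930 features x n echoes),
#' carrying over the per-echo metadata.
#'
#' @param echoSet An [EchoSet-class].
#' @return An [EchoSpectrogramSet-class].
#' @export
computeSpectrograms <- function(echoSet) {
  stopifnot(is(echoSet, "EchoSet"))
  wf <- SummarizedExperiment::assay(echoSet, "waveform")
  sr <- S4Vectors::metadata(echoSet)$sampleRate %||% 1e6
  mat <- vapply(seq_len(ncol(wf)), function(j)
    flattenSpectrogram(computeSpectrogram(wf[, j], sr)), numeric(930L))
  rd <- S4Vectors::DataFrame(
    freqHz = rep(SPECTRO_FREQS, each = SPECTRO_NFRAMES),
    frame = rep(seq_len(SPECTRO_NFRAMES), times = 10L)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectro = mat), rowData = rd,
    colData = SummarizedExperiment::colData(echoSet),
    metadata = c(S4Vectors::metadata(echoSet),
                 list(window = SPECTRO_WINDOW, hop = SPECTRO_HOP,
                      band = c(60e3, 150e3)))
  )
  colnames(se) <- colnames(echoSet)
  new("EchoSpectrogramSet", se)
}

#' @describeIn EchoSpectrogram-class Compact display.
#' @param object An `EchoSpectrogram`.
#' @export
setMethod("show", "EchoSpectrogram", function(object) {
  cat(sprintf(
    "EchoSpectrogram: %d frequency rows (%.0f-%.0f kHz) x %d frames (%.1f ms span)\n",
    nrow(object@mat), min(object@freqAxis) / 1e3, max(object@freqAxis) / 1e3,
    ncol(object@mat), diff(range(object@timeAxis)) * 1e3))
})
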