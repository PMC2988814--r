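#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

#' Simulated biosonar emission click
#'
#' A windowed tone burst emulating the emission signal of an echolocating
#' odontocete. The dolphin-like style is short (70 microseconds) and broadband
#' with a 130 kHz spectral peak; the porpoise-like style is long
#' (270 microseconds) and narrowband with a 138 kHz peak.
#'
#' @slot samples Numeric waveform, peak absolute amplitude 1. The vector spans
#'   exactly the burst support (no leading/trailing zeros).
#' @slot sampleRate Sampling rate in Hz.
#' @slot style `"dolphin"` or `"porpoise"`.
#' @slot peakFrequency Carrier / spectral peak frequency in Hz.
#' @slot nominalDuration Burst support in seconds.
#' @slot nCycles Carrier cycles completed within the support
#'   (`peakFrequency * nominalDuration`).
#'
#' @seealso [makeClick()]
#' @export
setClass("EmissionSignal",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    style = "character",
    peakFrequency = "numeric",
    nominalDuration = "numeric",
    nCycles = "numeric"
  )
)

setValidity("EmissionSignal", function(object) {
  msg <- character()
  if (length(object@samples) < 2L)
    msg <- c(msg, "waveform must contain at least 2 samples")
  if (object@sampleRate <= 2 * object@peakFrequency)
    msg <- c(msg, "sampleRate must exceed twice the peak frequency (Nyquist)")
  if (abs(max(abs(object@samples)) - 1) > 1e-12)
    msg <- c(msg, "peak absolute amplitude must be normalized to 1")
  nz <- which(object@samples != 0)
  support <- if (length(nz)) max(nz) - min(nz) + 1L else 0L
  nominal <- round(object@nominalDuration * object@sampleRate)
  if (abs(support - nominal) > 1L)
    msg <- c(msg, sprintf(
      "waveform support (%d samples) must equal nominal duration (%d samples) within 1 sample",
      support, nominal))
  if (length(msg)) msg else TRUE
})

#' Aspect-dependent point-reflector model of a fish
#'
#' A small set of internal reflectors (swim bladder, skeletal surfaces,
#' internal propagation paths) stands in for the acoustic anatomy of one
#' species. Each reflector delays, band-pass filters and scales the incident
#' click; delays and gains are modulated by the aspect angle, and
#' individual-level anatomy is drawn by jittering the base parameters.
#'
#' @slot name Species label.
#' @slot reflectors List of reflectors; each is a list with elements
#'   `baseDelay` (s), `delayAspectAmp` (s), `delayPhase` (rad), `baseGain`,
#'   `gainLobe`, `gainPhase` (rad), `filterCenter` (Hz), `filterBandwidth`
#'   (Hz).
#' @slot individualJitter Named numeric fractional standard deviations
#'   (`delay`, `gain`, `center`) applied per individual.
#' @slot bodyLengthRange Body length range in cm (metadata only).
#'
#' @seealso [speciesPreset()], [synthesizeEcho()]
#' @export
setClass("SpeciesModel",
  representation(
    name = "character",
    reflectors = "list",
    individualJitter = "numeric",
    bodyLengthRange = "numeric"
  )
)

setValidity("SpeciesModel", function(object) {
  msg <- character()
  if (length(object@reflectors) < 1L)
    msg <- c(msg, "model needs at least one reflector")
  need <- c("baseDelay", "delayAspectAmp", "delayPhase", "baseGain",
            "gainLobe", "gainPhase", "filterCenter", "filterBandwidth")
  for (r in object@reflectors) {
    if (!all(need %in% names(r))) {
      msg <- c(msg, paste("reflector missing fields:",
                          paste(setdiff(need, names(r)), collapse = ", ")))
      next
    }
    if (r$baseDelay < 0 || r$baseDelay > 1024e-6)
      msg <- c(msg, "reflector base delay must lie within the 1024-sample echo window")
    if (r$filterCenter < 60e3 || r$filterCenter > 150e3)
      msg <- c(msg, "reflector filter center must lie in the 60-150 kHz band")
  }
  if (!all(c("delay", "gain", "center") %in% names(object@individualJitter)))
    msg <- c(msg, "individualJitter needs named entries delay, gain, center")
  else if (any(object@individualJitter < 0))
    msg <- c(msg, "jitter SDs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Container for a set of simulated (or measured) fish echoes
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"waveform"` holds one 1024-sample echo per column (1 MHz sampling).
#' `colData` carries species, individual, acquisition angle, aspect sector and
#' the per-ping noise seed; `metadata` records the generator configuration and
#' master seed so a dataset can be regenerated bit-for-bit.
#'
#' @seealso [generateEchoSet()], [readEchoSet()], [writeEchoSet()]
#' @export
setClass("EchoSet", contains = "SummarizedExperiment")

setValidity("EchoSet", function(object) {
  msg <- character()
  if (nrow(object) != 1024L)
    msg <- c(msg, "echoes must have exactly 1024 samples (rows)")
  if (!"waveform" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'waveform' is required")
  need <- c("species", "individual", "angle", "aspect")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && ncol(object) > 0) {
    cd <- SummarizedExperiment::colData(object)
    if (!all(cd$aspect == assignAspect(cd$angle)))
      msg <- c(msg, "aspect labels inconsistent with assignAspect(angle)")
  }
  if (length(msg)) msg else TRUE
})

#' Band-limited, dB-scaled, max-normalized echo spectrogram
#'
#' The classifier input representation: short-time magnitude spectra with a
#' 100-point Hann window and 90% overlap, restricted to the 60-150 kHz band
#' audible to dolphins and porpoises, converted to dB and affinely rescaled so
#' the maximum is exactly 1. Geometry is fixed at 10 frequency rows
#' (60..150 kHz in 10 kHz steps) by 93 time frames for a 1024-sample echo.
#'
#' @slot mat 10 x 93 numeric matrix in [0, 1], maximum exactly 1.
#' @slot freqAxis Row center frequencies in Hz.
#' @slot timeAxis Frame center times in seconds.
#'
#' @seealso [computeSpectrogram()], [flattenSpectrogram()]
#' @export
setClass("EchoSpectrogram",
  representation(mat = "matrix", freqAxis = "numeric", timeAxis = "numeric")
)

setValidity("EchoSpectrogram", function(object) {
  msg <- character()
  if (!all(dim(object@mat) == c(10L, 93L)))
    msg <- c(msg, "spectrogram must be 10 frequency rows x 93 time frames")
  if (any(object@mat < 0) || any(object@mat > 1))
    msg <- c(msg, "spectrogram values must lie in [0, 1]")
  if (abs(max(object@mat) - 1) > 1e-12)
    msg <- c(msg, "spectrogram maximum must be exactly 1")
  if (length(msg)) msg else TRUE
})

#' Container for a stack of flattened echo spectrograms
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay `"spectro"`
#' holds one flattened 930-element spectrogram per column (row-major: all 93
#' frames of the 60 kHz row first). `rowData` carries the frequency/time
#' coordinate of each element; `colData` is inherited from the source
#' [EchoSet].
#'
#' @seealso [computeSpectrograms()]
#' @export
setClass("EchoSpectrogramSet", contains = "SummarizedExperiment")

setValidity("EchoSpectrogramSet", function(object) {
  msg <- character()
  if (nrow(object) != 930L)
    msg <- c(msg, "flattened spectrograms must have 930 elements (10 x 93)")
  if (!"spectro" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectro' is required")
  if (length(msg)) msg else TRUE
})

#' Quadratic discriminant model over envelope features
#'
#' Class-conditional Gaussian model: per-class mean vectors and covariance
#' matrices (ridge-regularized), class priors, and quadratic discriminant
#' scoring.
#'
#' @slot means List of per-class mean vectors.
#' @slot covariances List of per-class covariance matrices (after ridge).
#' @slot priors Named numeric class priors, summing to 1.
#' @slot ridge Ridge fraction added as `ridge * mean(diag(S))` to covariance
#'   diagonals.
#' @slot featureNames Feature names in training order.
#'
#' @seealso [fitQda()], [predictQda()]
#' @export
setClass("QDAModel",
  representation(
    means = "list",
    covariances = "list",
    priors = "numeric",
    ridge = "numeric",
    featureNames = "character"
  )
)

setValidity("QDAModel", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "class priors must sum to 1")
  for (S in object@covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "covariances must be positive definite after regularization")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validated classification performance for one task
#'
#' Per-repeat accuracies (percent), their mean and SD, the chance level of the
#' task, and a one-sided t-test p-value against chance.
#'
#' @slot task Human-readable task descriptor.
#' @slot accuracies Percent accuracy per cross-validation repeat.
#' @slot chance Chance level in percent.
#' @slot pValue One-sided p-value of mean accuracy > chance.
#' @slot degenerate TRUE when the repeat accuracies have zero variance and the
#'   t statistic is undefined (p is then an exact limit).
#'
#' @seealso [crossvalidateDfa()], [runSvmTask()], [testVsChance()]
#' @export
setClass("ClassificationResult",
  representation(
    task = "character",
    accuracies = "numeric",
    chance = "numeric",
    pValue = "numeric",
    degenerate = "logical"
  )
)

setValidity("ClassificationResult", function(object) {
  msg <- character()
  # a repeat is NA when the task's test draw contained no echo of the class
  if (any(object@accuracies < 0 | object@accuracies > 100, na.rm = TRUE))
    msg <- c(msg, "accuracies must lie in [0, 100] percent")
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Linear maximum-margin spectrogram classifier
#'
#' A soft-margin linear separator over flattened spectrograms. The decision
#' rule is exactly `sign(<w, x> + offset)`: positive maps to the positive
#' class, negative to the other; an exact zero is assigned to the positive
#' class.
#'
#' @slot w Weight vector (length 930 for spectrogram tasks: the flattened
#'   decision echo).
#' @slot offset Scalar offset b.
#' @slot cost Soft-margin penalty C used in training.
#' @slot taskType `"pairwise"` or `"one_vs_all"`.
#' @slot positive,negative Class labels mapped to the two signs.
#'
#' @seealso [trainLinearSvm()], [classifySpectrograms()], [decisionEcho()]
#' @export
setClass("LinearDecisionModel",
  representation(
    w = "numeric",
    offset = "numeric",
    cost = "numeric",
    taskType = "character",
    positive = "character",
    negative = "character"
  )
)

setValidity("LinearDecisionModel", function(object) {
  if (length(object@w) < 1L)
    "weight vector must be non-empty" else TRUE
})

#' Decision echo: the classifier's weight vector in spectrogram geometry
#'
#' The learned weight vector reshaped to the 10 x 93 spectrogram grid. Regions
#' of high absolute weight mark the spectro-temporal features that drive the
#' species decision. Smoothing with a unit-sum Gaussian kernel removes
#' high-frequency structure that may be a small-sample artifact.
#'
#' @slot weights 10 x 93 weight matrix.
#' @slot offset Scalar offset of the originating model.
#' @slot smoothed Whether the Gaussian smoothing has been applied.
#' @slot kernelSize,kernelSigma Smoothing kernel parameters (pixels).
#' @slot freqAxis,timeAxis Axes inherited from the spectrogram geometry.
#'
#' @seealso [decisionEcho()], [smoothDecisionEcho()]
#' @export
setClass("DecisionEcho",
  representation(
    weights = "matrix",
    offset = "numeric",
    smoothed = "logical",
    kernelSize = "integer",
    kernelSigma = "numeric",
    freqAxis = "numeric",
    timeAxis = "numeric"
  )
)

setValidity("DecisionEcho", function(object) {
  if (!all(dim(object@weights) == c(10L, 93L)))
    "decision echo must be a 10 x 93 matrix" else TRUE
})

#' Eigen-fish basis of one species' spectrograms
#'
#' The per-species principal decomposition used for synthetic resampling: the
#' mean spectrogram vector, the first k orthonormal eigen-vectors
#' ("eigen-fishes"), and the standard deviations of the training projections
#' on each component.
#'
#' @slot species Species label.
#' @slot center Mean spectrogram vector (length 930).
#' @slot vectors 930 x k matrix of orthonormal components.
#' @slot sds Projection SDs, non-increasing.
#'
#' @seealso [eigenfishBasis()], [resampleEigenfish()]
#' @export
setClass("EigenFishBasis",
  representation(
    species = "character",
    center = "numeric",
    vectors = "matrix",
    sds = "numeric"
  )
)

setValidity("EigenFishBasis", function(object) {
  msg <- character()
  k <- ncol(object@vectors)
  if (length(object@sds) != k)
    msg <- c(msg, "one projection SD per component is required")
  G <- crossprod(object@vectors)
  if (max(abs(G - diag(k))) > 1e-8)
    msg <- c(msg, "eigen-vectors must be orthonormal")
  if (any(diff(object@sds) > 1e-8) || any(object@sds < 0))
    msg <- c(msg, "projection SDs must be non-negative and non-increasing")
  if (length(msg)) msg else TRUE
})
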