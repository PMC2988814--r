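# Minimal mono RIFF/WAVE codec. Synthetic echoes are written as 32-bit IEEE
# float samples (format code 3) to avoid quantizing them; 16-bit PCM (format
# code 1) is also read. No installed package provides WAV I/O, so the few
# dozen lines live here.

#' Write a mono waveform as a WAV file
#'
#' Samples are stored as 32-bit IEEE floats so synthetic waveforms survive a
#' round trip bit-for-bit.
#'
#' @param samples Numeric waveform.
#' @param path Output file path.
#' @param sampleRate Sampling rate in Hz.
#' @export
writeWav <- function(samples, path, sampleRate = 1e6) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  dataBytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")              # IEEE float
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")              # block align
  writeBin(32L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 32-bit IEEE float and 16-bit PCM mono files.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric) and `sampleRate` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop(path, ": not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop(path, ": not a WAVE file")
  fmt <- NULL; samples <- NULL; rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")  # byte rate
      readBin(con, integer(), n = 2, size = 2, endian = "little")  # align, bits
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop(path, ": data chunk before fmt chunk")
      if (fmt[2] != 1L) stop(path, ": only mono WAV files are supported")
      if (fmt[1] == 3L) {
        samples <- readBin(con, numeric(), n = size / 4L, size = 4,
                           endian = "little")
      } else if (fmt[1] == 1L) {
        samples <- readBin(con, integer(), n = size / 2L, size = 2,
                           endian = "little", signed = TRUE) / 32768
      } else stop(path, ": unsupported WAV format code ", fmt[1])
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(samples)) stop(path, ": no data chunk found")
  list(samples = samples, sampleRate = rate)
}

#' Write an echo set as a directory of WAV files plus a CSV manifest
#'
#' One WAV file per echo plus `manifest.csv` with columns filename, species,
#' individual, angle_deg, aspect, emission_style, seed, and a JSON sidecar
#' `dataset.json` with the generator configuration.
#'
#' @param echoSet An [EchoSet-class].
#' @param path Output directory (created if needed).
#' @export
writeEchoSet <- function(echoSet, path) {
  stopifnot(is(echoSet, "EchoSet"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cd <- SummarizedExperiment::colData(echoSet)
  wf <- SummarizedExperiment::assay(echoSet, "waveform")
  sr <- S4Vectors::metadata(echoSet)$sampleRate %||% 1e6
  files <- sprintf("echo_%04d.wav", seq_len(ncol(echoSet)))
  for (j in seq_len(ncol(echoSet)))
    writeWav(wf[, j], file.path(path, files[j]), sr)
  manifest <- data.frame(
    filename = files,
    species = cd$species,
    individual = cd$individual,
    angle_deg = round(cd$angle, 1),
    aspect = cd$aspect,
    emission_style = cd$emissionStyle,
    seed = cd$pingSeed
  )
  utils::write.csv(manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(S4Vectors::metadata(echoSet),
                       file.path(path, "dataset.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an echo set from a WAV directory plus CSV manifest
#'
#' Validates every record: the manifest columns must be present, each WAV
#' file must exist, be sampled at 1 MHz and contain exactly 1024 samples;
#' violations raise an error naming the offending record.
#'
#' @param path Directory written by [writeEchoSet()].
#' @return An [EchoSet-class].
#' @export
readEchoSet <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("manifest.csv not found in ", path)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("filename", "species", "individual", "angle_deg", "aspect",
            "emission_style", "seed")
  miss <- setdiff(need, colnames(manifest))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  wf <- matrix(0, 1024L, nrow(manifest))
  rate <- NULL
  for (j in seq_len(nrow(manifest))) {
    f <- file.path(path, manifest$filename[j])
    if (!file.exists(f)) stop("missing echo file: ", manifest$filename[j])
    w <- readWav(f)
    if (length(w$samples) != 1024L)
      stop(sprintf("%s: expected 1024 samples, got %d",
                   manifest$filename[j], length(w$samples)))
    if (w$sampleRate != 1e6)
      stop(sprintf("%s: expected a 1 MHz sample rate, got %g Hz",
                   manifest$filename[j], w$sampleRate))
    wf[, j] <- w$samples
    rate <- w$sampleRate
  }
  meta <- list(sampleRate = rate %||% 1e6)
  js <- file.path(path, "dataset.json")
  if (file.exists(js))
    meta <- utils::modifyList(jsonlite::read_json(js, simplifyVector = TRUE),
                              meta)
  angles <- manifest$angle_deg
  angularStep <- meta$angularStep %||% {
    u <- sort(unique(angles)); if (length(u) > 1L) min(diff(u)) else 1
  }
  cd <- S4Vectors::DataFrame(
    species = manifest$species, individual = manifest$individual,
    angle = angles, angleIndex = as.integer(round(angles / angularStep)),
    aspect = manifest$aspect, emissionStyle = manifest$emission_style,
    pingSeed = manifest$seed
  )
  meta$nAngles <- meta$nAngles %||% as.integer(round(360 / angularStep))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(waveform = wf), colData = cd, metadata = meta)
  colnames(se) <- sprintf("%s_a%05.1f", cd$individual, cd$angle)
  new("EchoSet", se)
}

#' Write an emission signal as WAV plus a JSON sidecar
#'
#' @param signal An [EmissionSignal-class].
#' @param path WAV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
writeEmissionSignal <- function(signal, path) {
  stopifnot(is(signal, "EmissionSignal"))
  writeWav(signal@samples, path, signal@sampleRate)
  jsonlite::write_json(
    list(style = signal@style, peakFrequency = signal@peakFrequency,
         nominalDuration = signal@nominalDuration, nCycles = signal@nCycles,
         sampleRate = signal@sampleRate),
    sub("\\.wav$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an emission signal written by [writeEmissionSignal()]
#'
#' @param path WAV path with an accompanying `.json` sidecar.
#' @return An [EmissionSignal-class].
#' @export
readEmissionSignal <- function(path) {
  w <- readWav(path)
  side <- jsonlite::read_json(sub("\\.wav$", ".json", path),
                              simplifyVector = TRUE)
  new("EmissionSignal", samples = w$samples, sampleRate = w$sampleRate,
      style = side$style, peakFrequency = side$peakFrequency,
      nominalDuration = side$nominalDuration, nCycles = side$nCycles)
}
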