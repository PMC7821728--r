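#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' VoltageBlock: one block of raw multichannel voltage
#'
#' A single continuous recording block as acquired: a channels x samples
#' matrix of voltages (microvolts) at a fixed sampling rate, with each row
#' identified by its clinical electrode number.
#'
#' @slot blockId block identifier (e.g. `"008"`).
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelNumbers integer vector of electrode numbers, one per row.
#'
#' @export
setClass("VoltageBlock",
  slots = c(
    blockId = "character",
    data = "matrix",
    sampleRate = "numeric",
    channelNumbers = "integer"
  )
)

setValidity("VoltageBlock", function(object) {
  msg <- character()
  if (length(object@blockId) != 1L || !nzchar(object@blockId))
    msg <- c(msg, "blockId must be a single non-empty string")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (nrow(object@data) != length(object@channelNumbers))
    msg <- c(msg, sprintf(
      "channelNumbers (%d) must align 1:1 with matrix rows (%d)",
      length(object@channelNumbers), nrow(object@data)))
  if (anyDuplicated(object@channelNumbers))
    msg <- c(msg, "channelNumbers must be unique")
  if (length(object@channelNumbers) && any(object@channelNumbers < 1L))
    msg <- c(msg, "channelNumbers must be positive (1-based)")
  bad <- which(!stats::complete.cases(object@data) |
                 apply(object@data, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    msg <- c(msg, sprintf("non-finite samples in channel(s): %s",
                          paste(object@channelNumbers[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a VoltageBlock
#'
#' @param blockId block identifier.
#' @param data channels x samples numeric matrix (microvolts).
#' @param sampleRate sampling rate in Hz.
#' @param channelNumbers electrode number of each row (1-based).
#' @return A [VoltageBlock-class] object.
#' @export
VoltageBlock <- function(blockId, data, sampleRate, channelNumbers) {
  new("VoltageBlock", blockId = as.character(blockId),
      data = as.matrix(data), sampleRate = as.numeric(sampleRate),
      channelNumbers = as.integer(channelNumbers))
}

#' WaveletBank: a set of complex Morlet kernels
#'
#' Each kernel is a complex exponential at one centre frequency under a
#' Gaussian envelope, truncated to `duration = cycles / frequency` seconds
#' and normalized to unit energy.
#'
#' @slot frequencies centre frequencies in Hz (strictly increasing).
#' @slot cycles number of oscillation cycles per kernel.
#' @slot durations kernel durations in seconds (`cycles / frequencies`).
#' @slot kernels list of complex vectors (odd length, unit energy).
#' @slot designRate sampling rate (Hz) the kernels were sampled at.
#'
#' @export
setClass("WaveletBank",
  slots = c(
    frequencies = "numeric",
    cycles = "numeric",
    durations = "numeric",
    kernels = "list",
    designRate = "numeric"
  )
)

setValidity("WaveletBank", function(object) {
  msg <- character()
  K <- length(object@frequencies)
  if (length(object@cycles) != K || length(object@durations) != K ||
      length(object@kernels) != K)
    msg <- c(msg, "frequencies, cycles, durations, kernels must have equal length")
  if (K > 1 && any(diff(object@frequencies) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (K > 1 && any(diff(object@cycles) < 0))
    msg <- c(msg, "cycles must be nondecreasing with frequency")
  if (any(object@cycles <= 0)) msg <- c(msg, "cycles must be positive")
  if (K && max(abs(object@durations - object@cycles / object@frequencies)) > 1e-12)
    msg <- c(msg, "durations must equal cycles / frequencies")
  energies <- vapply(object@kernels, function(k) sum(Mod(k)^2), numeric(1))
  if (K && any(abs(energies - 1) > 1e-9))
    msg <- c(msg, "each kernel must have unit energy (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' SpectralArray: complex wavelet coefficients for one electrode
#'
#' The unit of storage and referencing: a frequency x time matrix of complex
#' coefficients. Both real and imaginary parts are always kept, which is
#' what allows re-referencing to be applied after spectral decomposition.
#'
#' @slot electrode electrode number.
#' @slot coefficients complex matrix, frequency x time.
#' @slot frequencies Hz, strictly increasing, one per row.
#' @slot spectralRate sampling rate of the time axis (Hz).
#' @slot reference description of the applied reference scheme, or `"none"`.
#' @slot validMask logical matrix, same shape; FALSE marks samples within
#'   half a kernel duration of a block edge (zero-padding contamination).
#'
#' @export
setClass("SpectralArray",
  slots = c(
    electrode = "integer",
    coefficients = "matrix",
    frequencies = "numeric",
    spectralRate = "numeric",
    reference = "character",
    validMask = "matrixOrNULL"
  ),
  prototype = list(reference = "none", validMask = NULL)
)

setValidity("SpectralArray", function(object) {
  msg <- character()
  if (!is.complex(object@coefficients))
    msg <- c(msg, "coefficients must be complex (real and imaginary parts preserved)")
  if (nrow(object@coefficients) != length(object@frequencies))
    msg <- c(msg, "one coefficient row per frequency required")
  if (length(object@frequencies) > 1 && any(diff(object@frequencies) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@spectralRate) != 1L || object@spectralRate <= 0)
    msg <- c(msg, "spectralRate must be a single positive number")
  if (!is.null(object@validMask) &&
      !identical(dim(object@validMask), dim(object@coefficients)))
    msg <- c(msg, "validMask must match coefficients in shape")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralArray
#'
#' @param electrode electrode number.
#' @param coefficients complex frequency x time matrix.
#' @param frequencies Hz vector, one per row.
#' @param spectralRate time-axis sampling rate in Hz.
#' @param reference reference description (default `"none"`).
#' @param validMask optional logical matrix marking edge-valid samples.
#' @return A [SpectralArray-class] object.
#' @export
SpectralArray <- function(electrode, coefficients, frequencies, spectralRate,
                          reference = "none", validMask = NULL) {
  if (!is.complex(coefficients)) storage.mode(coefficients) <- "complex"
  new("SpectralArray", electrode = as.integer(electrode),
      coefficients = coefficients, frequencies = as.numeric(frequencies),
      spectralRate = as.numeric(spectralRate),
      reference = as.character(reference), validMask = validMask)
}

#' TrialTensor: epoched, baseline-transformable power for one electrode
#'
#' A trial x frequency x time array of power (or of a baseline-normalized
#' unit after [baselineTransform()]) plus the matching phase array, time
#' axis relative to the locking event (0 = event), and per-trial metadata.
#'
#' @slot electrode electrode number.
#' @slot power trial x frequency x time array. Non-negative while
#'   `unit == "power"`; may be signed after baseline transformation.
#' @slot phase same-shape array of phase angles (radians).
#' @slot timeAxis seconds relative to the locking event.
#' @slot frequencies Hz.
#' @slot trialMeta data.frame with columns `trial_number`, `block`,
#'   `condition`, `is_outlier` (one row per trial).
#' @slot lockingEvent name of the event the epochs are time-locked to.
#' @slot unit `"power"` or a baseline unit name.
#'
#' @export
setClass("TrialTensor",
  slots = c(
    electrode = "integer",
    power = "array",
    phase = "array",
    timeAxis = "numeric",
    frequencies = "numeric",
    trialMeta = "data.frame",
    lockingEvent = "character",
    unit = "character"
  )
)

setValidity("TrialTensor", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 3L) msg <- c(msg, "power must be a 3-d array (trial x frequency x time)")
  else {
    if (!identical(dim(object@phase), d))
      msg <- c(msg, "phase must match power in shape")
    if (d[2] != length(object@frequencies))
      msg <- c(msg, "second dimension must match frequencies")
    if (d[3] != length(object@timeAxis))
      msg <- c(msg, "third dimension must match timeAxis")
    if (nrow(object@trialMeta) != d[1])
      msg <- c(msg, "trialMeta must have one row per trial")
  }
  need <- c("trial_number", "block", "condition", "is_outlier")
  miss <- setdiff(need, names(object@trialMeta))
  if (length(miss))
    msg <- c(msg, paste("trialMeta lacks column(s):", paste(miss, collapse = ", ")))
  if (identical(object@unit, "power") && length(object@power) &&
      min(object@power) < -1e-12)
    msg <- c(msg, "power must be non-negative when unit == \"power\"")
  if (length(object@timeAxis) > 1) {
    dt <- diff(object@timeAxis)
    if (max(abs(dt - dt[1])) > 1e-9)
      msg <- c(msg, "timeAxis must be uniformly sampled")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceScheme: a re-referencing rule
#'
#' @slot kind one of `"none"`, `"common_average"`, `"white_matter"`,
#'   `"bipolar"`.
#' @slot electrodes reference set (common average / white matter kinds).
#' @slot pairs data.frame with columns `anode`, `cathode`, `derived`,
#'   `label` (bipolar kind).
#'
#' @export
setClass("ReferenceScheme",
  slots = c(kind = "character", electrodes = "integer", pairs = "data.frame"),
  prototype = list(electrodes = integer(), pairs = data.frame())
)

setValidity("ReferenceScheme", function(object) {
  msg <- character()
  kinds <- c("none", "common_average", "white_matter", "bipolar")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (object@kind %in% c("common_average", "white_matter") &&
      length(object@electrodes) < 1L)
    msg <- c(msg, "reference electrode set must be nonempty")
  if (identical(object@kind, "bipolar")) {
    need <- c("anode", "cathode", "derived", "label")
    if (!all(need %in% names(object@pairs)))
      msg <- c(msg, "bipolar pairs need columns anode, cathode, derived, label")
    else if (nrow(object@pairs) &&
             any(object@pairs$anode == object@pairs$cathode))
      msg <- c(msg, "bipolar pairs must reference distinct electrodes")
  }
  if (length(msg)) msg else TRUE
})

#' SubjectStore: handle to one subject's on-disk data tree
#'
#' The directory layout is project at the highest level, then subject, then
#' data files, with `raw/`, `spectral/` and `meta/` subfolders per subject.
#'
#' @slot root project root directory.
#' @slot project project name.
#' @slot subject subject identifier.
#'
#' @export
setClass("SubjectStore",
  slots = c(root = "character", project = "character", subject = "character")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "VoltageBlock", function(object) {
  cat(sprintf("VoltageBlock '%s': %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              object@blockId, nrow(object@data), ncol(object@data),
              object@sampleRate, ncol(object@data) / object@sampleRate))
  cat("  electrodes:", paste(utils::head(object@channelNumbers, 10), collapse = ", "),
      if (length(object@channelNumbers) > 10) "...", "\n")
})

setMethod("show", "WaveletBank", function(object) {
  cat(sprintf("WaveletBank: %d kernels @ %g Hz design rate\n",
              length(object@frequencies), object@designRate))
  cat(sprintf("  frequencies %.3g-%.3g Hz, cycles %g-%g, durations %.3f-%.3f s\n",
              min(object@frequencies), max(object@frequencies),
              min(object@cycles), max(object@cycles),
              min(object@durations), max(object@durations)))
})

setMethod("show", "SpectralArray", function(object) {
  cat(sprintf("SpectralArray electrode %d: %d frequencies x %d samples @ %g Hz\n",
              object@electrode, nrow(object@coefficients),
              ncol(object@coefficients), object@spectralRate))
  cat("  reference:", object@reference, "\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@power)
  cat(sprintf("TrialTensor electrode %d: %d trials x %d frequencies x %d timepoints\n",
              object@electrode, d[1], d[2], d[3]))
  cat(sprintf("  unit: %s; locked to '%s'; t in [%.3f, %.3f] s; %d outlier trial(s)\n",
              object@unit, object@lockingEvent, min(object@timeAxis),
              max(object@timeAxis), sum(object@trialMeta$is_outlier)))
})

setMethod("show", "ReferenceScheme", function(object) {
  cat("ReferenceScheme:", object@kind, "\n")
  if (object@kind %in% c("common_average", "white_matter"))
    cat("  reference electrodes:", paste(object@electrodes, collapse = ", "), "\n")
  if (identical(object@kind, "bipolar"))
    cat("  pairs:", nrow(object@pairs), "\n")
})

setMethod("show", "SubjectStore", function(object) {
  cat(sprintf("SubjectStore: %s / %s / %s\n",
              object@root, object@project, object@subject))
})
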