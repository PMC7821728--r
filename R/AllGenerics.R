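#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("channelNumbers", function(x) standardGeneric("channelNumbers"))
#' @rdname accessors
#' @export
setGeneric("voltageData", function(x) standardGeneric("voltageData"))
#' @rdname accessors
#' @export
setGeneric("electrode", function(x) standardGeneric("electrode"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("spectralCoefs", function(x) standardGeneric("spectralCoefs"))
#' @rdname accessors
#' @export
setGeneric("spectralRate", function(x) standardGeneric("spectralRate"))
#' @rdname accessors
#' @export
setGeneric("referenceApplied", function(x) standardGeneric("referenceApplied"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("trialMeta", function(x) standardGeneric("trialMeta"))
#' @rdname accessors
#' @export
setGeneric("powerArray", function(x) standardGeneric("powerArray"))
#' @rdname accessors
#' @export
setGeneric("phaseArray", function(x) standardGeneric("phaseArray"))
#' @rdname accessors
#' @export
setGeneric("analysisUnit", function(x) standardGeneric("analysisUnit"))
#' @rdname accessors
#' @export
setGeneric("kernels", function(x) standardGeneric("kernels"))
#' @rdname accessors
#' @export
setGeneric("cycles", function(x) standardGeneric("cycles"))
#' @rdname accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' @rdname accessors
#' @export
setMethod("blockId", "VoltageBlock", function(x) x@blockId)
#' @rdname accessors
#' @export
setMethod("sampleRate", "VoltageBlock", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("channelNumbers", "VoltageBlock", function(x) x@channelNumbers)
#' @rdname accessors
#' @export
setMethod("voltageData", "VoltageBlock", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("frequencies", "WaveletBank", function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("cycles", "WaveletBank", function(x) x@cycles)
#' @rdname accessors
#' @export
setMethod("durations", "WaveletBank", function(x) x@durations)
#' @rdname accessors
#' @export
setMethod("kernels", "WaveletBank", function(x) x@kernels)
#' @rdname accessors
#' @export
setMethod("sampleRate", "WaveletBank", function(x) x@designRate)

#' @rdname accessors
#' @export
setMethod("electrode", "SpectralArray", function(x) x@electrode)
#' @rdname accessors
#' @export
setMethod("frequencies", "SpectralArray", function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("spectralCoefs", "SpectralArray", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("spectralRate", "SpectralArray", function(x) x@spectralRate)
#' @rdname accessors
#' @export
setMethod("referenceApplied", "SpectralArray", function(x) x@reference)
#' @rdname accessors
#' @export
setMethod("validMask", "SpectralArray", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("electrode", "TrialTensor", function(x) x@electrode)
#' @rdname accessors
#' @export
setMethod("frequencies", "TrialTensor", function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("timeAxis", "TrialTensor", function(x) x@timeAxis)
#' @rdname accessors
#' @export
setMethod("trialMeta", "TrialTensor", function(x) x@trialMeta)
#' @rdname accessors
#' @export
setMethod("powerArray", "TrialTensor", function(x) x@power)
#' @rdname accessors
#' @export
setMethod("phaseArray", "TrialTensor", function(x) x@phase)
#' @rdname accessors
#' @export
setMethod("analysisUnit", "TrialTensor", function(x) x@unit)
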