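#' @import methods
NULL

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("clampMode", function(x) standardGeneric("clampMode"))

#' @export
setGeneric("stimulus", function(x) standardGeneric("stimulus"))

#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))

#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @export
setGeneric("sweepSets", function(x) standardGeneric("sweepSets"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @export
setGeneric("sweepMetadata", function(x) standardGeneric("sweepMetadata"))

#' @export
setGeneric("bandPower", function(x, ...) standardGeneric("bandPower"))
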