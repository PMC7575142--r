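#' Construct a Trace
#'
#' @param samples numeric signal vector (mV in current clamp, pA in voltage
#'   clamp).
#' @param samplingRate sampling rate, Hz.
#' @param clampMode `"current_clamp"` or `"voltage_clamp"`.
#' @param t0 time of the first sample, s.
#' @param stimulus optional command channel, same length as `samples`
#'   (pA for injected current, 0-1 for light intensity).
#' @return a [Trace-class] object.
#' @examples
#' tr <- Trace(rnorm(1000), samplingRate = 10000)
#' nSamples(tr)
#' @export
Trace <- function(samples, samplingRate = 10000,
                  clampMode = c("current_clamp", "voltage_clamp"),
                  t0 = 0, stimulus = numeric()) {
  clampMode <- match.arg(clampMode)
  new("Trace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate), clampMode = clampMode,
      t0 = as.numeric(t0), stimulus = as.numeric(stimulus))
}

#' @describeIn Trace signal vector.
#' @param x a `Trace`.
#' @export
setMethod("samples", "Trace", function(x) x@samples)

#' @describeIn Trace sampling rate in Hz.
#' @export
setMethod("samplingRate", "Trace", function(x) x@samplingRate)

#' @describeIn Trace clamp mode string.
#' @export
setMethod("clampMode", "Trace", function(x) x@clampMode)

#' @describeIn Trace stimulus channel (possibly empty).
#' @export
setMethod("stimulus", "Trace", function(x) x@stimulus)

#' @describeIn Trace sample times in seconds.
#' @export
setMethod("traceTimes", "Trace", function(x)
  x@t0 + (seq_along(x@samples) - 1) / x@samplingRate)

#' @describeIn Trace number of samples.
#' @export
setMethod("nSamples", "Trace", function(x) length(x@samples))

#' @describeIn Trace signal units implied by the clamp mode.
#' @export
setMethod("traceUnits", "Trace", function(x)
  if (x@clampMode == "current_clamp") "mV" else "pA")

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples @ %g kHz, %s (%s), t0 = %g s%s\n",
              length(object@samples), object@samplingRate / 1000,
              object@clampMode, traceUnits(object), object@t0,
              if (length(object@stimulus)) ", with stimulus channel" else ""))
})

#' @describeIn ProtocolSweepSet protocol name.
#' @param x a `ProtocolSweepSet`.
#' @export
setMethod("protocol", "ProtocolSweepSet", function(x) x@protocol)

#' @describeIn ProtocolSweepSet list of per-trial trace groups.
#' @export
setMethod("trials", "ProtocolSweepSet", function(x) x@trials)

#' @describeIn ProtocolSweepSet metadata list.
#' @export
setMethod("sweepMetadata", "ProtocolSweepSet", function(x) x@metadata)

setMethod("show", "ProtocolSweepSet", function(object) {
  ncell <- if (length(object@trials)) length(object@trials[[1]]) else 0L
  cat(sprintf("ProtocolSweepSet '%s': %d trial(s) x %d cell(s)\n",
              object@protocol, length(object@trials), ncell))
})

#' Construct a ProtocolSweepSet
#'
#' @param protocol protocol name (see [ProtocolSweepSet-class]).
#' @param trials list of named lists of [Trace], one element per trial.
#' @param metadata named list of protocol particulars.
#' @return a [ProtocolSweepSet-class] object.
#' @export
ProtocolSweepSet <- function(protocol, trials, metadata = list()) {
  new("ProtocolSweepSet", protocol = protocol, trials = trials,
      metadata = metadata)
}
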