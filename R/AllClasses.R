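## Central S4 containers.
##
## Unit conventions, fixed package-wide: voltage in mV, current in pA,
## distance in um, frequency in Hz.  Time is stored in seconds everywhere;
## user-facing summaries report latencies and kinetics in ms.  Raw
## voltage-clamp currents keep physiological sign (inward negative at a
## -60 mV holding potential); all reported "amplitudes" are magnitudes.

.CLAMP_MODES <- c("current_clamp", "voltage_clamp")
.PROTOCOLS   <- c("ap_train", "current_step", "light_pulse", "light_ramp",
                  "spontaneous")
.CELL_LABELS <- c("ORX", "MCH", "VGLUT2", "GAD65-GFP", "GAD65-cre", "VGAT",
                  "PV/FS", "NPY", "pyramidal", "n.m.")
.REGIONS     <- c("LH", "mPFC")

#' Trace: one uniformly sampled recorded or simulated signal
#'
#' A single sweep from one cell: membrane potential (mV) in current clamp
#' or membrane current (pA) in voltage clamp, with an optional stimulus
#' command channel of the same length (pA for injected current, 0-1
#' normalized light intensity for optical stimuli).
#'
#' @slot samples numeric vector of signal values (mV or pA by clamp mode).
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot clampMode `"current_clamp"` or `"voltage_clamp"`.
#' @slot t0 time of the first sample, in seconds.
#' @slot stimulus numeric vector of command values, either empty or the
#'   same length as `samples`.
#' @exportClass Trace
setClass("Trace",
  representation(samples = "numeric", samplingRate = "numeric",
                 clampMode = "character", t0 = "numeric",
                 stimulus = "numeric"),
  prototype(samples = numeric(), samplingRate = 10000,
            clampMode = "current_clamp", t0 = 0, stimulus = numeric()))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive finite number")
  if (length(object@clampMode) != 1L ||
      !object@clampMode %in% .CLAMP_MODES)
    msg <- c(msg, sprintf("clampMode must be one of: %s",
                          paste(.CLAMP_MODES, collapse = ", ")))
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(object@stimulus) &&
      length(object@stimulus) != length(object@samples))
    msg <- c(msg, "stimulus length must equal samples length")
  if (length(msg)) msg else TRUE
})

#' ProtocolSweepSet: simultaneous sweeps grouped by protocol
#'
#' One stimulus protocol run over a set of simultaneously recorded cells.
#' `trials` is a list (one element per trial) of named lists of [Trace]
#' objects keyed by cell id; all traces within a trial share sampling rate
#' and length.  `metadata` carries protocol particulars: for `ap_train`
#' the imposed spike times (`ap_times`, s) and the driven cell (`pre_id`);
#' for `current_step` the step window (`step_window`, s) and amplitude;
#' for `light_pulse`/`light_ramp` the light onset times (`light_times`, s).
#'
#' @slot protocol one of `"ap_train"`, `"current_step"`, `"light_pulse"`,
#'   `"light_ramp"`, `"spontaneous"`.
#' @slot trials list of named lists of `Trace`.
#' @slot metadata free-form named list.
#' @exportClass ProtocolSweepSet
setClass("ProtocolSweepSet",
  representation(protocol = "character", trials = "list",
                 metadata = "list"),
  prototype(protocol = "spontaneous", trials = list(), metadata = list()))

setValidity("ProtocolSweepSet", function(object) {
  msg <- character()
  if (length(object@protocol) != 1L || !object@protocol %in% .PROTOCOLS)
    msg <- c(msg, sprintf("protocol must be one of: %s",
                          paste(.PROTOCOLS, collapse = ", ")))
  for (i in seq_along(object@trials)) {
    tr <- object@trials[[i]]
    if (!is.list(tr) || is.null(names(tr)) || any(!nzchar(names(tr)))) {
      msg <- c(msg, sprintf("trials[[%d]] must be a named list of Trace", i))
      next
    }
    if (!all(vapply(tr, is, logical(1), class2 = "Trace"))) {
      msg <- c(msg, sprintf("trials[[%d]] contains non-Trace elements", i))
      next
    }
    ns <- vapply(tr, function(x) length(x@samples), integer(1))
    rs <- vapply(tr, function(x) x@samplingRate, numeric(1))
    if (length(unique(ns)) > 1L)
      msg <- c(msg, sprintf(
        "trials[[%d]]: simultaneous traces have mismatched lengths", i))
    if (length(unique(rs)) > 1L)
      msg <- c(msg, sprintf(
        "trials[[%d]]: simultaneous traces have mismatched sampling rates", i))
  }
  if (object@protocol == "ap_train" &&
      is.null(object@metadata$ap_times))
    msg <- c(msg, "ap_train sweep sets must store metadata$ap_times (s)")
  if (length(msg)) msg else TRUE
})

#' Session: cells, sweep sets and (for simulations) ground truth
#'
#' The top-level container tying a cell table to the protocol sweep sets
#' recorded from those cells.  Simulated sessions additionally carry a
#' `groundTruth` list with the generative connectivity:
#' `chem` (directed logical matrix), `chem_amp` (directed amplitude matrix,
#' mV or pA), `elec` (symmetric coupling-coefficient matrix) and
#' `opto_connected` (named integer vector: connected opsin+ presynaptic
#' sources per recorded cell), plus per-stage event bookkeeping.
#'
#' @slot cells data.frame with columns `cell_id`, `label`, `region`,
#'   `x_um`, `y_um`, `depth_um`, `opsin_positive`.
#' @slot sweepSets list of [ProtocolSweepSet].
#' @slot groundTruth list (empty for recorded data).
#' @exportClass Session
setClass("Session",
  representation(cells = "data.frame", sweepSets = "list",
                 groundTruth = "list"),
  prototype(cells = data.frame(), sweepSets = list(),
            groundTruth = list()))

setValidity("Session", function(object) {
  msg <- character()
  cl <- object@cells
  need <- c("cell_id", "label", "region", "x_um", "y_um", "depth_um",
            "opsin_positive")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    return(sprintf("cells table missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(cl$cell_id))
    msg <- c(msg, "cells: duplicated cell_id")
  if (nrow(cl) && any(cl$depth_um < 0, na.rm = TRUE))
    msg <- c(msg, "cells: depth_um must be >= 0")
  if (nrow(cl) && !all(cl$label %in% .CELL_LABELS))
    msg <- c(msg, sprintf("cells: label must be one of: %s",
                          paste(.CELL_LABELS, collapse = ", ")))
  if (nrow(cl) && !all(cl$region %in% .REGIONS))
    msg <- c(msg, "cells: region must be 'LH' or 'mPFC'")
  if (!all(vapply(object@sweepSets, is, logical(1),
                  class2 = "ProtocolSweepSet")))
    return("sweepSets must contain only ProtocolSweepSet objects")
  ids <- as.character(cl$cell_id)
  for (ss in object@sweepSets)
    for (tr in ss@trials) {
      unknown <- setdiff(names(tr), ids)
      if (length(unknown))
        msg <- c(msg, sprintf("trace group references unknown cell_id: %s",
                              paste(unknown, collapse = ", ")))
    }
  gt <- object@groundTruth
  for (nm in c("chem", "elec"))
    if (!is.null(gt[[nm]])) {
      m <- gt[[nm]]
      if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) != nrow(cl))
        msg <- c(msg, sprintf("ground_truth$%s must be square over cells", nm))
    }
  if (!is.null(gt$elec) && is.matrix(gt$elec) &&
      nrow(gt$elec) == ncol(gt$elec) && !isTRUE(all.equal(gt$elec, t(gt$elec))))
    msg <- c(msg, "ground_truth$elec must be symmetric")
  if (length(msg)) unique(msg) else TRUE
})

#' SpectralResult: time-frequency power of one sweep
#'
#' Short-time power spectral density (pA^2/Hz in voltage clamp) of a trace,
#' with band-integrated summaries of a baseline and a stimulation interval
#' once [bandPower()] / [rampPowerIncrease()] have been applied.
#'
#' @slot times window-center times, s.
#' @slot freqs frequency grid, Hz.
#' @slot power matrix `length(freqs)` x `length(times)`, density units.
#' @slot band analysis band (Hz pair), possibly `NA` before band analysis.
#' @slot baselinePower,rampPower band-integrated mean power (signal-units^2)
#'   over the baseline / stimulation interval (`NA` until computed).
#' @slot increase `rampPower - baselinePower` (`NA` until computed).
#' @exportClass SpectralResult
setClass("SpectralResult",
  representation(times = "numeric", freqs = "numeric", power = "matrix",
                 band = "numeric", baselinePower = "numeric",
                 rampPower = "numeric", increase = "numeric"),
  prototype(band = c(NA_real_, NA_real_), baselinePower = NA_real_,
            rampPower = NA_real_, increase = NA_real_))

setValidity("SpectralResult", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freqs) ||
      ncol(object@power) != length(object@times))
    msg <- c(msg, "power must be length(freqs) x length(times)")
  if (length(object@power) && any(object@power < 0))
    msg <- c(msg, "power must be non-negative everywhere")
  if (length(msg)) msg else TRUE
})
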