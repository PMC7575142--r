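#' Construct a Session
#'
#' @param cells cell table from [cellTable()].
#' @param sweepSets list of [ProtocolSweepSet-class] objects.
#' @param groundTruth optional list of generative connectivity (simulation
#'   only); see [Session-class].
#' @return a validated [Session-class] object.
#' @export
Session <- function(cells, sweepSets = list(), groundTruth = list()) {
  new("Session", cells = cells, sweepSets = sweepSets,
      groundTruth = groundTruth)
}

#' @describeIn Session cell metadata table.
#' @param x a `Session`.
#' @export
setMethod("cells", "Session", function(x) x@cells)

#' @describeIn Session list of protocol sweep sets.
#' @export
setMethod("sweepSets", "Session", function(x) x@sweepSets)

#' @describeIn Session simulation ground truth (empty list for recordings).
#' @export
setMethod("groundTruth", "Session", function(x) x@groundTruth)

setMethod("show", "Session", function(object) {
  prot <- vapply(object@sweepSets, function(s) s@protocol, character(1))
  cat(sprintf("Session: %d cell(s), %d sweep set(s)%s\n",
              nrow(object@cells), length(object@sweepSets),
              if (length(object@groundTruth)) " [simulated, ground truth]"
              else ""))
  if (length(prot)) {
    tab <- table(prot)
    cat("  protocols:",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
})

## Container layout (format version 1): a serialized list
##   $format   "sparseconn-session"
##   $version  1L
##   $cells    data.frame           (cell metadata)
##   $sweeps   list of lists: protocol, metadata, trials; each trial a
##             named list (by cell_id) of lists with samples, sampling_rate,
##             clamp_mode, t0, stimulus
##   $ground_truth list
## All numeric fields round-trip at full double precision.

#' Write a Session container
#'
#' Serializes the session to a single self-contained container file with a
#' versioned layout (cell table, per-protocol trial groups keyed by cell
#' id, ground truth).  [readSession()] restores it field-for-field.
#'
#' @param session a [Session-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "Session"))
  validObject(session)
  enc <- list(
    format = "sparseconn-session", version = 1L,
    cells = session@cells,
    sweeps = lapply(session@sweepSets, function(ss) list(
      protocol = ss@protocol, metadata = ss@metadata,
      trials = lapply(ss@trials, function(tr)
        lapply(tr, function(x) list(
          samples = x@samples, sampling_rate = x@samplingRate,
          clamp_mode = x@clampMode, t0 = x@t0, stimulus = x@stimulus))))),
    ground_truth = session@groundTruth)
  saveRDS(enc, path)
  invisible(path)
}

#' Read a Session container
#'
#' @param path file written by [writeSession()].
#' @return a validated [Session-class].
#' @export
readSession <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  enc <- tryCatch(readRDS(path), error = function(e)
    stop("malformed session container '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(enc) || !identical(enc$format, "sparseconn-session"))
    stop("format error in '", path, "': field 'format' is not ",
         "'sparseconn-session'", call. = FALSE)
  if (!identical(enc$version, 1L))
    stop("format error in '", path, "': field 'version' unsupported",
         call. = FALSE)
  for (field in c("cells", "sweeps", "ground_truth"))
    if (is.null(enc[[field]]))
      stop("format error in '", path, "': field '", field, "' missing",
           call. = FALSE)
  sweepSets <- lapply(enc$sweeps, function(sw) {
    tr <- lapply(sw$trials, function(grp) lapply(grp, function(x) {
      stopifNotScalar(x$sampling_rate, "sampling_rate")
      new("Trace", samples = x$samples, samplingRate = x$sampling_rate,
          clampMode = x$clamp_mode, t0 = x$t0, stimulus = x$stimulus)
    }))
    new("ProtocolSweepSet", protocol = sw$protocol, trials = tr,
        metadata = sw$metadata)
  })
  out <- new("Session", cells = enc$cells, sweepSets = sweepSets,
             groundTruth = enc$ground_truth)
  msg <- validObject(out, test = TRUE)
  if (is.character(msg))
    stop("format error in '", path, "': ", msg[1], call. = FALSE)
  out
}
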