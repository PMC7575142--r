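#' Electrical coupling coefficient from a current step
#'
#' The gap-junction coupling coefficient: the steady-state voltage change
#' of the non-injected (postsynaptic) cell divided by the voltage change
#' of the injected (presynaptic) cell during a current step.  Steady-state
#' means use the last 20% of the step window; baselines use the segment
#' immediately preceding the step (up to 100 ms, with a 5 ms guard).
#'
#' @param pre_sweep,post_sweep current-clamp [Trace-class] sweeps recorded
#'   simultaneously (ideally trial averages).
#' @param step_window step onset/offset times, s.
#' @return the dimensionless coefficient, or `NA_real_` (with a warning
#'   and `attr(, "unreliable") = TRUE`) when the presynaptic deflection is
#'   below 1 mV and the ratio would be noise-dominated.
#' @examples
#' ## a -10 mV presynaptic step transferring -0.75 mV gives 0.075
#' @export
couplingCoefficient <- function(pre_sweep, post_sweep, step_window) {
  stopifnot(is(pre_sweep, "Trace"), is(post_sweep, "Trace"),
            length(step_window) == 2, step_window[2] > step_window[1])
  fs <- samplingRate(pre_sweep)
  deltaV <- function(tr) {
    x <- samples(tr)
    tt <- traceTimes(tr)
    base <- x[tt >= step_window[1] - 0.105 & tt < step_window[1] - 0.005]
    if (!length(base)) base <- x[tt < step_window[1]]
    if (!length(base)) stop("no baseline samples before the step")
    span <- step_window[2] - step_window[1]
    steady <- x[tt >= step_window[2] - 0.2 * span & tt < step_window[2]]
    mean(steady) - mean(base)
  }
  dv_pre <- deltaV(pre_sweep)
  dv_post <- deltaV(post_sweep)
  if (abs(dv_pre) < 1) {
    warning("presynaptic deflection below 1 mV; coefficient unreliable")
    out <- NA_real_
    attr(out, "unreliable") <- TRUE
    return(out)
  }
  dv_post / dv_pre
}

#' Coupling tests for every pair in a session
#'
#' Computes both directional coupling coefficients for each unordered
#' pair from the `current_step` sweep sets (trial-averaged), and calls a
#' pair electrically coupled when both coefficients exceed `threshold`
#' (bidirectional coupling, the reported phenotype; the default 0.005 sits
#' below the noise floor of typical steady-state estimates).
#'
#' @param session a [Session-class] with `current_step` sweep sets.
#' @param threshold coupling-coefficient detection threshold.
#' @return data.frame: `cell_a`, `cell_b`, `coeff_ab`, `coeff_ba`,
#'   `bidirectional`, `coupled`, `distance_um`.
#' @export
couplingTests <- function(session, threshold = 0.005) {
  stopifnot(is(session, "Session"))
  sets <- Filter(function(s) s@protocol == "current_step", session@sweepSets)
  if (!length(sets)) stop("session has no current_step sweep sets")
  cl <- session@cells
  ## directional coefficients keyed by pre -> post
  co <- list()
  for (ss in sets) {
    pre <- ss@metadata$pre_id
    win <- ss@metadata$step_window
    ids <- names(ss@trials[[1]])
    avg <- lapply(ids, function(id) averageTrials(lapply(ss@trials, `[[`, id)))
    names(avg) <- ids
    for (post in setdiff(ids, pre))
      co[[paste(pre, post, sep = "->")]] <-
        couplingCoefficient(avg[[pre]], avg[[post]], win)
  }
  ids <- cl$cell_id
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    ab <- co[[paste(ids[i], ids[j], sep = "->")]] %||% NA_real_
    ba <- co[[paste(ids[j], ids[i], sep = "->")]] %||% NA_real_
    bidir <- isTRUE(ab > threshold) && isTRUE(ba > threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_a = ids[i], cell_b = ids[j],
      coeff_ab = as.numeric(ab), coeff_ba = as.numeric(ba),
      bidirectional = bidir, coupled = bidir,
      distance_um = intersomaticDistance(cl, ids[i], ids[j]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
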