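#' Short-time power spectrum of a trace
#'
#' Computes a spectrogram with the analysis settings of the light-ramp
#' protocol: 0.5 s windows with 95% overlap after zero-phase high-pass
#' filtering at 10 Hz (4th-order Butterworth run forward and backward).
#' Each window is Hann-tapered; power is one-sided spectral *density*
#' (signal-units^2 per Hz) with the taper's power correction, so
#' integrating over frequency recovers the signal variance (Parseval).
#' The number of windows for a trace of duration `T` is
#' `floor((T - w) / (w * (1 - overlap))) + 1`.
#'
#' @param trace a [Trace-class] (typically voltage clamp, pA).
#' @param window_s window length, s.
#' @param overlap_frac fractional window overlap.
#' @param highpass_hz high-pass cutoff, Hz (0 disables filtering).
#' @return a [SpectralResult-class]; `times` are window centers.
#' @importFrom signal butter filtfilt
#' @export
spectrogramPower <- function(trace, window_s = 0.5, overlap_frac = 0.95,
                             highpass_hz = 10) {
  stopifnot(is(trace, "Trace"), window_s > 0,
            overlap_frac >= 0, overlap_frac < 1)
  fs <- samplingRate(trace)
  x <- samples(trace)
  n <- length(x)
  nw <- round(window_s * fs)
  if (n < nw) stop("trace is shorter than one analysis window")
  if (highpass_hz > 0) {
    bf <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  step <- max(1L, round(nw * (1 - overlap_frac)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / (nw - 1)))   # Hann taper
  wpow <- sum(w^2)
  seg <- vapply(starts, function(s) x[s:(s + nw - 1L)] * w, numeric(nw))
  X <- stats::mvfft(seg)
  nk <- nw %/% 2 + 1L
  p <- (Mod(X[seq_len(nk), , drop = FALSE])^2) * (2 / (fs * wpow))
  p[1, ] <- p[1, ] / 2                      # DC is not doubled
  if (nw %% 2 == 0) p[nk, ] <- p[nk, ] / 2  # nor Nyquist
  new("SpectralResult",
      times = trace@t0 + (starts - 1 + nw / 2) / fs,
      freqs = (seq_len(nk) - 1) * fs / nw,
      power = p, band = c(NA_real_, NA_real_),
      baselinePower = NA_real_, rampPower = NA_real_, increase = NA_real_)
}

#' @describeIn spectrogramPower Mean band-integrated power over a time
#'   interval.  Integrates the spectral density over the half-open
#'   frequency band `[band[1], band[2])` by the trapezoidal rule and
#'   averages across the spectrogram windows whose centers fall in
#'   `interval`; the result is in signal-units^2 (pA^2 for voltage clamp).
#' @param x a [SpectralResult-class].
#' @param band frequency band, Hz (half-open `[lo, hi)`).
#' @param interval time interval, s; `NULL` means all windows.
#' @export
setMethod("bandPower", "SpectralResult",
  function(x, band = c(10, 80), interval = NULL) {
    stopifnot(length(band) == 2, band[2] > band[1])
    sel_t <- if (is.null(interval)) rep(TRUE, length(x@times))
             else x@times >= interval[1] & x@times < interval[2]
    if (!any(sel_t)) stop("no spectrogram windows in the given interval")
    sel_f <- x@freqs >= band[1] & x@freqs < band[2]
    if (sum(sel_f) < 2) stop("band covers fewer than two frequency bins")
    f <- x@freqs[sel_f]
    pw <- x@power[sel_f, sel_t, drop = FALSE]
    ## trapezoidal integration over frequency, then mean over windows
    df <- diff(f)
    integ <- colSums((pw[-1, , drop = FALSE] +
                      pw[-nrow(pw), , drop = FALSE]) / 2 * df)
    mean(integ)
  })

#' Band-power increase during a light ramp, per cell
#'
#' For every cell of every `light_ramp` sweep set: spectrogram of each
#' sweep, power averaged across sweeps (power-domain averaging is
#' insensitive to the oscillation's trial-varying phase and damps the
#' band-power contribution of occasional large spontaneous PSCs), then
#' band-integrated power over the baseline interval (by default the 1 s
#' immediately preceding ramp onset) and over the ramp interval (by
#' default the full ramp), and their difference.  This is the per-cell
#' quantity whose group contrast separates an oscillating network from a
#' non-oscillating one.
#'
#' @param session a [Session-class] with `light_ramp` sweep sets whose
#'   metadata carries `ramp_onset_s` and `ramp_duration_s`.
#' @param band analysis band, Hz.
#' @param baseline_interval,ramp_interval explicit intervals (s pairs),
#'   or `NULL` for the defaults above.
#' @param window_s,overlap_frac,highpass_hz spectrogram settings.
#' @return data.frame: `cell_id`, `baseline_power`, `ramp_power`,
#'   `increase` (all in pA^2), with group mean/sd in
#'   `attr(, "summary")`.
#' @export
rampPowerIncrease <- function(session, band = c(10, 80),
                              baseline_interval = NULL,
                              ramp_interval = NULL, window_s = 0.5,
                              overlap_frac = 0.95, highpass_hz = 10) {
  stopifnot(is(session, "Session"))
  sets <- Filter(function(s) s@protocol == "light_ramp", session@sweepSets)
  if (!length(sets)) stop("session has no light_ramp sweep sets")
  rows <- list()
  for (ss in sets) {
    onset <- ss@metadata$ramp_onset_s
    dur <- ss@metadata$ramp_duration_s
    if (is.null(onset) || is.null(dur))
      stop("light_ramp metadata must carry ramp_onset_s and ramp_duration_s")
    bi <- baseline_interval %||% c(onset - 1, onset)
    ri <- ramp_interval %||% c(onset, onset + dur)
    for (id in names(ss@trials[[1]])) {
      sweeps <- lapply(ss@trials, `[[`, id)
      if (bi[1] < sweeps[[1]]@t0 - 1e-9)
        stop("baseline interval starts before the recording")
      specs <- lapply(sweeps, spectrogramPower, window_s = window_s,
                      overlap_frac = overlap_frac,
                      highpass_hz = highpass_hz)
      sp <- specs[[1]]
      if (length(specs) > 1) {
        acc <- Reduce(`+`, lapply(specs, function(s) s@power))
        sp@power <- acc / length(specs)
      }
      bp <- bandPower(sp, band = band, interval = bi)
      rp <- bandPower(sp, band = band, interval = ri)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, baseline_power = bp, ramp_power = rp,
        increase = rp - bp, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(mean_increase = mean(out$increase),
                               sd_increase = stats::sd(out$increase),
                               n = nrow(out))
  out
}
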