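## Template-based PSC detection.  One algorithm serves both spontaneous
## and optogenetically evoked currents; classification into kinds happens
## afterwards from the light times alone, so the two populations are
## measured identically.

## valid cross-correlation of y with template g via FFT:
## r[k] = sum_j g[j] * y[k + j - 1], k = 1 .. n - ng + 1
crossCorrTemplate <- function(y, g) {
  n <- length(y); ng <- length(g)
  nfft <- stats::nextn(n + ng, 2)
  Y <- stats::fft(c(y, numeric(nfft - n)))
  G <- stats::fft(c(g, numeric(nfft - ng)))
  r <- Re(stats::fft(Y * Conj(G), inverse = TRUE)) / nfft
  r[seq_len(n - ng + 1)]
}

#' Detect postsynaptic-current events by template matching
#'
#' Slides a unit-peak difference-of-exponentials template along the
#' (polarity-rectified, slow-drift-corrected) trace; the normalized
#' matched-filter response at alignment `k` estimates the amplitude of an
#' event with onset there.  Local maxima of the response above
#' `threshold_sd` robust noise sds are events; maxima closer together
#' than `min_sep_ms` merge into one *compound* (multiphasic) event, while
#' peaks at least `min_sep_ms` apart stay separate events.  Detections
#' whose half-width is narrower than `min_halfwidth_ms` are discarded as
#' action-current artifacts.
#'
#' Amplitudes are reported as magnitudes (pA).  Simple events take the
#' matched-filter amplitude estimate (noise-optimal, unbiased for
#' isolated events); compound events take the full peak of the lightly
#' smoothed trace over the event span, measured from the local pre-onset
#' baseline, and their kinetics are flagged unavailable.
#'
#' @param trace a voltage-clamp [Trace-class].
#' @param polarity expected event polarity: `"inward"` (negative currents,
#'   e.g. EPSCs at -60 mV) or `"outward"` (IPSCs at 0 mV).  Required.
#' @param rise_ms,decay_ms template kinetics (defaults match the
#'   simulator's kernel).
#' @param threshold_sd detection threshold in robust (MAD) sds of the
#'   matched-filter response.
#' @param min_sep_ms peak separation below which maxima merge into one
#'   compound event.
#' @param min_halfwidth_ms artifact veto: minimum half-width of a real
#'   PSC, ms.
#' @param drift_window_s running-median window for slow-baseline removal.
#' @return data.frame of events: `onset_s`, `peak_s`, `peak_amp_pA`,
#'   `rise_ms`, `decay_tau_ms`, `halfwidth_ms`, `compound`, `kind`
#'   (all `"spontaneous"` until [classifyOpto()]), `criterion`.  Aligned
#'   snippets are attached as `attr(, "snippets")` (each starting 5 ms
#'   before onset), with `attr(, "sampling_rate")`.
#' @export
detectEvents <- function(trace, polarity, rise_ms = 1.5, decay_ms = 8,
                         threshold_sd = 4, min_sep_ms = 5,
                         min_halfwidth_ms = 1, drift_window_s = 0.3) {
  stopifnot(is(trace, "Trace"))
  if (missing(polarity) || !polarity %in% c("inward", "outward"))
    stop("polarity must be 'inward' or 'outward'")
  fs <- samplingRate(trace)
  sgn <- if (polarity == "inward") -1 else 1
  y <- sgn * samples(trace)
  n <- length(y)
  ## slow drift removal (tonic currents, holding-current wander)
  k <- min(2L * floor(drift_window_s * fs / 2) + 1L,
           2L * floor((n - 1) / 2) + 1L)
  if (k >= 3) y <- y - stats::runmed(y, k)

  ng <- min(n, ceiling(6 * decay_ms / 1000 * fs))
  g <- pscKernel(seq(0, by = 1 / fs, length.out = ng), rise_ms, decay_ms)
  tr_ms <- rise_ms / 1000; td_ms <- decay_ms / 1000
  tpk_n <- round(tr_ms * td_ms / (td_ms - tr_ms) * log(td_ms / tr_ms) * fs)

  m <- crossCorrTemplate(y, g) / sum(g^2)
  sig <- stats::mad(m)
  thr <- threshold_sd * sig
  nm <- length(m)
  if (nm < 3) return(emptyEventFrame(fs))

  ## stage 1 -- detection: local maxima of the matched-filter response
  ## above threshold, with a +/- min_sep exclusion zone (strongest first)
  is_max <- c(FALSE, m[2:(nm - 1)] >= m[1:(nm - 2)] &
                     m[2:(nm - 1)] > m[3:nm], FALSE)
  cand <- which(is_max & m > thr)
  if (!length(cand)) return(emptyEventFrame(fs))
  sep_n <- round(min_sep_ms / 1000 * fs)
  ord <- cand[order(m[cand], decreasing = TRUE)]
  principal <- integer(0)
  for (k0 in ord)
    if (!length(principal) || all(abs(principal - k0) >= sep_n))
      principal <- c(principal, k0)
  principal <- sort(principal)

  ## light smoothing for raw-trace measures (1.1 ms boxcar)
  bw <- max(3L, round(0.0011 * fs))
  ysm <- as.numeric(stats::filter(y, rep(1 / bw, bw), sides = 2))
  pre_n <- round(0.005 * fs)
  ms1 <- round(0.001 * fs)

  ## stage 2 -- rise decomposition: within each detection's span, peaks of
  ## the rising slope mark successive release phases.  The matched
  ## filter's autocorrelation is too broad to resolve close events, and a
  ## second event arriving during the rise produces no dip in the trace
  ## at all -- but every release phase has its own slope maximum.
  slope <- c(NA, diff(ysm)) * fs                 # signal units per second
  slope_noise <- stats::mad(slope, na.rm = TRUE)
  riseOnsets <- function(lo, hi) {
    seg <- slope[lo:hi]
    sm <- length(seg)
    pk <- which(c(FALSE, seg[2:(sm - 1)] >= seg[1:(sm - 2)] &
                         seg[2:(sm - 1)] > seg[3:sm], FALSE) &
                !is.na(seg))
    if (!length(pk)) return(integer(0))
    big <- pk[seg[pk] >= max(0.25 * max(seg[pk]), 6 * slope_noise)]
    if (!length(big)) return(integer(0))
    ## merge slope peaks closer than the kernel rise time
    merge_n <- max(1L, round(rise_ms / 1000 * fs))
    keep <- integer(0)
    for (p in big[order(seg[big], decreasing = TRUE)])
      if (!length(keep) || all(abs(keep - p) >= merge_n)) keep <- c(keep, p)
    sort(keep) + lo - 1L
  }

  ## a detection's true first rise can precede the matched-filter maximum
  ## (merged bumps peak between overlapping events), so each detection
  ## searches a window reaching back past the kernel's rise-to-peak time;
  ## duplicates across windows collapse via unique()
  phases_all <- integer(0)
  for (j in seq_along(principal)) {
    k0 <- principal[j]
    lo <- max(1L, k0 - tpk_n - round(0.002 * fs))
    hi <- min(n, k0 + ng - 1L,
              if (j < length(principal)) principal[j + 1] + tpk_n else n)
    phases_all <- c(phases_all, riseOnsets(lo, hi))
  }
  phases_all <- sort(unique(phases_all))

  event_list <- list()
  if (length(phases_all)) {
    ## group rise phases: gaps >= min_sep start a new event
    grp <- cumsum(c(1L, diff(phases_all) >= sep_n))
    for (g in split(phases_all, grp))
      event_list[[length(event_list) + 1L]] <-
        list(align = as.integer(max(1, g[1] - round(0.5 * rise_ms / 1000 * fs))),
             phases = g)
  }
  ## detections whose vicinity yielded no usable rise keep a single event
  for (k0 in principal)
    if (!length(phases_all) ||
        !any(phases_all >= k0 - tpk_n - round(0.002 * fs) &
             phases_all <= k0 + ng))
      event_list[[length(event_list) + 1L]] <-
        list(align = k0, phases = min(n, k0 + tpk_n))
  if (!length(event_list)) return(emptyEventFrame(fs))
  event_list <- event_list[order(vapply(event_list, function(e)
    as.numeric(e$align), numeric(1)))]

  rows <- vector("list", length(event_list))
  snippets <- vector("list", length(event_list))
  for (i in seq_along(event_list)) {
    a0 <- min(event_list[[i]]$align, nm)
    phases <- event_list[[i]]$phases
    compound <- length(phases) > 1
    base_hi <- max(1L, a0 - round(0.0005 * fs))
    base <- stats::median(y[max(1L, a0 - pre_n):base_hi])
    ## peak: maximum of the smoothed trace over the event span
    span_hi <- min(n, max(phases) + tpk_n + round(0.002 * fs))
    seg <- ysm[a0:span_hi]
    if (all(is.na(seg))) next
    pk_idx <- a0 + which.max(seg) - 1L
    ## amplitude: the matched-filter estimate is noise-optimal but assumes
    ## a clean baseline; compound peaks and events riding on another
    ## event's decay tail are measured from the raw (smoothed) peak
    ## relative to their local pre-onset level instead
    amp_m <- max(m[max(1L, a0 - ms1):min(nm, a0 + ms1)])
    amp_raw <- ysm[pk_idx] - base
    amp <- if (compound || !is.finite(amp_m) ||
               abs(base) > 0.25 * max(amp_m, amp_raw)) amp_raw else amp_m
    if (!is.finite(amp) || amp <= 0) next
    ## half-width veto against brief action-current artifacts
    half <- base + amp / 2
    iL <- pk_idx; while (iL > 1 && !is.na(ysm[iL - 1]) && ysm[iL - 1] > half)
      iL <- iL - 1L
    iR <- pk_idx; while (iR < n && !is.na(ysm[iR + 1]) && ysm[iR + 1] > half)
      iR <- iR + 1L
    halfwidth_ms <- (iR - iL + 1) / fs * 1000
    if (halfwidth_ms < min_halfwidth_ms) next   # artifact: drop

    ## onset convention: 10%-of-peak crossing before the first phase peak
    lev <- base + 0.1 * amp
    i10 <- min(pk_idx, phases[1] + round(rise_ms / 1000 * fs))
    while (i10 > 1 && !is.na(ysm[i10 - 1]) && ysm[i10 - 1] > lev)
      i10 <- i10 - 1L
    frac <- if (i10 > 1 && !is.na(ysm[i10 - 1]) && ysm[i10] != ysm[i10 - 1])
      (lev - ysm[i10 - 1]) / (ysm[i10] - ysm[i10 - 1]) else 0
    onset_idx <- (i10 - 1L) + frac

    snip_lo <- max(1L, a0 - pre_n)
    snip <- y[snip_lo:min(n, a0 + ng - 1L)] - base
    kin <- if (compound) c(NA_real_, NA_real_)
           else fitKinetics(snip, fs, pre_samples = a0 - snip_lo)
    rows[[i]] <- data.frame(
      onset_s = trace@t0 + (onset_idx - 1) / fs,
      peak_s = trace@t0 + (pk_idx - 1) / fs,
      peak_amp_pA = amp, rise_ms = kin[1], decay_tau_ms = kin[2],
      halfwidth_ms = halfwidth_ms, compound = compound,
      kind = "spontaneous",
      criterion = max(m[max(1L, a0 - ms1):min(nm, a0 + ms1)]) / sig,
      stringsAsFactors = FALSE)
    snippets[[i]] <- snip
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(emptyEventFrame(fs))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  attr(out, "snippets") <- snippets[keep]
  attr(out, "sampling_rate") <- fs
  attr(out, "polarity") <- polarity
  out
}

emptyEventFrame <- function(fs) {
  out <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                    peak_amp_pA = numeric(0), rise_ms = numeric(0),
                    decay_tau_ms = numeric(0), halfwidth_ms = numeric(0),
                    compound = logical(0), kind = character(0),
                    criterion = numeric(0), stringsAsFactors = FALSE)
  attr(out, "snippets") <- list()
  attr(out, "sampling_rate") <- fs
  out
}

#' Fit PSC kinetics from an aligned snippet
#'
#' 20-80% rise time (linear interpolation on the rising limb) and decay
#' time constant by least-squares single-exponential fit from the peak.
#' The snippet should contain the full decay to at most 20% of peak.
#'
#' @param snippet numeric vector, positive-going event, baseline first.
#' @param sampling_rate Hz.
#' @param pre_samples number of pre-onset baseline samples at the start.
#' @return `c(rise_ms, decay_tau_ms)`; `NA`s if the fit fails (the event
#'   is kept by callers, its kinetics just unavailable).
#' @export
fitKinetics <- function(snippet, sampling_rate, pre_samples = 0L) {
  tryCatch({
    base <- if (pre_samples >= 3) stats::median(snippet[seq_len(pre_samples)])
            else 0
    z <- snippet - base
    pk <- which.max(z)
    amp <- z[pk]
    if (!is.finite(amp) || amp <= 0) return(c(NA_real_, NA_real_))
    interpCross <- function(level) {
      below <- which(z[seq_len(pk)] < level)
      if (!length(below)) return(NA_real_)
      i <- max(below)
      if (i >= pk) return(NA_real_)
      i + (level - z[i]) / (z[i + 1] - z[i])
    }
    t20 <- interpCross(0.2 * amp); t80 <- interpCross(0.8 * amp)
    rise_ms <- (t80 - t20) / sampling_rate * 1000
    ## decay: least-squares single exponential fitted in the linear domain
    ## on the falling limb, from the 50%-of-peak point down to the 5%
    ## crossing.  The fit window is selected by time on a lightly smoothed
    ## copy (value-based selection of noisy samples would bias tau up),
    ## and the 50% start excludes the peak region where the rising
    ## exponential still flattens the decay.
    tail <- z[pk:length(z)]
    bw <- max(3L, round(0.0011 * sampling_rate))
    sm <- as.numeric(stats::filter(tail, rep(1 / bw, bw), sides = 2))
    a <- max(sm, na.rm = TRUE)
    i0 <- which(sm <= 0.5 * a)[1]
    iend <- which(sm <= 0.05 * a)[1]
    if (is.na(iend)) iend <- length(tail)
    if (is.na(i0) || iend - i0 < 5) return(c(rise_ms, NA_real_))
    tt <- (i0:iend - 1) / sampling_rate
    yy <- tail[i0:iend]
    lf <- stats::lm(log(pmax(sm[i0:iend], 1e-9 * a)) ~ tt)
    tau0 <- -1 / stats::coef(lf)[2]
    if (!is.finite(tau0) || tau0 <= 0) return(c(rise_ms, NA_real_))
    fit <- tryCatch(stats::nls(yy ~ A * exp(-tt / tau),
                               start = list(A = 2 * a, tau = tau0)),
                    error = function(e) NULL)
    tau <- if (is.null(fit)) tau0 else stats::coef(fit)[["tau"]]
    if (!is.finite(tau) || tau <= 0) return(c(rise_ms, NA_real_))
    c(rise_ms, 1000 * tau)
  }, error = function(e) c(NA_real_, NA_real_))
}

#' Classify detected events as optogenetic or spontaneous
#'
#' Events whose onset falls within `window_ms` after a light pulse are
#' optogenetically evoked; all others are spontaneous.  The default 1-20
#' ms window bounds the monosynaptic latency regime.  Detection itself is
#' untouched: both kinds come from the same [detectEvents()] run.
#'
#' @param events data.frame from [detectEvents()].
#' @param light_times light pulse onset times, s (must not produce
#'   overlapping windows).
#' @param window_ms acceptance window after each pulse, ms.
#' @return `events` with `kind` set and, for optogenetic events,
#'   `light_time_s` and `latency_ms` filled in.
#' @export
classifyOpto <- function(events, light_times, window_ms = c(1, 20)) {
  stopifnot(length(window_ms) == 2, window_ms[2] > window_ms[1])
  light_times <- sort(light_times)
  if (length(light_times) >= 2 &&
      any(diff(light_times) < (window_ms[2] - window_ms[1]) / 1000))
    stop("light windows overlap; cannot attribute events uniquely")
  events$kind <- "spontaneous"
  events$light_time_s <- NA_real_
  events$latency_ms <- NA_real_
  if (!nrow(events) || !length(light_times)) return(events)
  for (i in seq_len(nrow(events))) {
    dt <- events$onset_s[i] - light_times
    hit <- which(dt >= window_ms[1] / 1000 & dt <= window_ms[2] / 1000)
    if (length(hit)) {
      events$kind[i] <- "optogenetic"
      events$light_time_s[i] <- light_times[hit[1]]
      events$latency_ms[i] <- latencyMs(events$onset_s[i],
                                        light_times[hit[1]])
    }
  }
  events
}

#' Latency from light onset to response onset
#'
#' @param onset_s event onset time(s) (10%-of-peak crossing), s.
#' @param light_time_s light pulse onset, s.
#' @return latency in ms; errors if any onset precedes the light.
#' @export
latencyMs <- function(onset_s, light_time_s) {
  if (any(onset_s < light_time_s))
    stop("event onset precedes the light pulse")
  (onset_s - light_time_s) * 1000
}
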