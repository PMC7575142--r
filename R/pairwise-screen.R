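#' Average simultaneous trials
#'
#' Pointwise mean of repeated sweeps (the screening protocol averages
#' 30-50 trials; white noise sd scales as `1/sqrt(N)`).
#'
#' @param trial_traces list of [Trace-class] of equal length and rate.
#' @return a [Trace-class] holding the mean trace.
#' @export
averageTrials <- function(trial_traces) {
  stopifnot(length(trial_traces) >= 1)
  ns <- vapply(trial_traces, nSamples, integer(1))
  rs <- vapply(trial_traces, samplingRate, numeric(1))
  if (length(unique(ns)) > 1L)
    stop("cannot average trials of mixed lengths")
  if (length(unique(rs)) > 1L)
    stop("cannot average trials with mixed sampling rates")
  m <- rowMeans(vapply(trial_traces, samples, numeric(ns[1])))
  st <- trial_traces[[1]]@stimulus
  Trace(m, samplingRate = rs[1], clampMode = trial_traces[[1]]@clampMode,
        t0 = trial_traces[[1]]@t0, stimulus = st)
}

## cache of Monte-Carlo calibrated threshold factors, keyed by
## (window samples, local-baseline samples, n_ap, alpha)
.calibCache <- new.env(parent = emptyenv())

## Null statistic of the evoked-response rule: for unit-sd white noise,
## per AP take the extreme deviation (after local-baseline subtraction) in
## the window; choose the majority polarity; the statistic is the mean of
## the per-AP peaks in that direction.  The factor returned is the
## (1 - alpha) null quantile in baseline-sd units.  Uses an isolated RNG
## stream so calibration never perturbs the caller's seed.
calibratedThresholdFactor <- function(m_win, m_base, n_ap, alpha,
                                      nsim = 4000) {
  key <- paste(m_win, m_base, n_ap, signif(alpha, 6), sep = "|")
  hit <- .calibCache[[key]]
  if (!is.null(hit)) return(hit)
  stat <- withLocalSeed(760813L, {
    vapply(seq_len(nsim), function(i) {
      pk <- matrix(0, n_ap, 2)
      for (a in seq_len(n_ap)) {
        dev <- stats::rnorm(m_win) - mean(stats::rnorm(m_base))
        pk[a, ] <- c(max(dev), min(dev))
      }
      pol <- ifelse(pk[, 1] > -pk[, 2], 1, -1)
      p <- if (sum(pol > 0) >= n_ap / 2) 1 else -1
      if (p > 0) mean(pk[, 1]) else mean(-pk[, 2])
    }, numeric(1))
  })
  q <- as.numeric(stats::quantile(stat, 1 - alpha, names = FALSE))
  .calibCache[[key]] <- q
  q
}

#' Detect an evoked response in a trial-averaged trace
#'
#' Screens one putative connection from the averaged postsynaptic trace of
#' an action-potential train protocol.  For each presynaptic spike, the
#' peak deviation from a local pre-spike baseline within `window_ms` is
#' taken; the response amplitude is the mean of these peaks in the
#' majority polarity.  A connection is called when (i) the amplitude
#' exceeds the detection threshold and (ii) the deflection polarity is
#' consistent across at least 3 of 5 spikes (60% generally).
#'
#' The threshold is `k_sd` x the baseline sd of the averaged trace when
#' `k_sd` is given.  By default (`k_sd = NULL`) the factor is calibrated
#' by an internal Monte-Carlo null of the exact peak statistic so that the
#' criterion has false-positive probability `alpha` per tested connection:
#' a fixed small `k_sd` is badly miscalibrated for a windowed-peak
#' statistic, because the maximum of hundreds of baseline-noise samples
#' routinely exceeds 3 sd.
#'
#' @param mean_trace averaged [Trace-class] (see [averageTrials()]).
#' @param ap_times imposed presynaptic spike times, s.
#' @param window_ms response window after each spike, ms (default 1-20).
#' @param k_sd fixed threshold factor, or `NULL` for calibrated (default).
#' @param alpha nominal per-test false-positive probability used when
#'   calibrating the default threshold.
#' @param baseline_guard_ms gap between a spike and its local baseline, ms.
#' @return list with `detected`, `evoked_amp` (magnitude, trace units),
#'   `latency_ms` (spike peak to 10%-of-peak crossing; `NA` if not
#'   detected), `polarity` (+1/-1), `baseline_sd`, `threshold`,
#'   `n_consistent`.
#' @export
detectEvokedResponse <- function(mean_trace, ap_times,
                                 window_ms = c(1, 20), k_sd = NULL,
                                 alpha = 0.01, baseline_guard_ms = 0.5) {
  stopifnot(is(mean_trace, "Trace"), length(ap_times) >= 1)
  fs <- samplingRate(mean_trace)
  x <- samples(mean_trace)
  t0 <- mean_trace@t0
  first_ap <- min(ap_times)
  if (first_ap - t0 < 0.05)
    stop("baseline before the first spike must be at least 50 ms")
  bl_idx <- seq_len(max(1L, floor((first_ap - t0 - 0.002) * fs)))
  sigma <- stats::sd(x[bl_idx])
  w <- window_ms / 1000
  m_base <- max(2L, round(0.0025 * fs))    # 2.5 ms local baseline
  guard <- baseline_guard_ms / 1000
  n_ap <- length(ap_times)

  pk <- matrix(NA_real_, n_ap, 2)
  dev_list <- vector("list", n_ap)
  for (a in seq_len(n_ap)) {
    i_ap <- round((ap_times[a] - t0) * fs) + 1L
    ib <- max(1L, i_ap - round(guard * fs) - m_base):(i_ap - round(guard * fs))
    iw <- (i_ap + round(w[1] * fs)):min(length(x), i_ap + round(w[2] * fs))
    dev <- x[iw] - mean(x[ib])
    dev_list[[a]] <- dev
    pk[a, ] <- c(max(dev), min(dev))
  }
  pol_ap <- ifelse(pk[, 1] > -pk[, 2], 1, -1)
  polarity <- if (sum(pol_ap > 0) >= n_ap / 2) 1 else -1
  n_consistent <- sum(pol_ap == polarity)
  amp <- if (polarity > 0) mean(pk[, 1]) else mean(-pk[, 2])

  m_win <- length(dev_list[[1]])
  factor <- if (is.null(k_sd))
    calibratedThresholdFactor(m_win, m_base, n_ap, alpha) else k_sd
  threshold <- factor * sigma
  need <- min(3L, n_ap)
  detected <- (amp > threshold) && (n_consistent >= max(need, 0.6 * n_ap))

  latency_ms <- NA_real_
  if (detected) {
    ## AP-triggered average response, 10%-of-peak crossing
    len <- min(lengths(dev_list))
    avg <- polarity * rowMeans(vapply(dev_list, function(d) d[seq_len(len)],
                                      numeric(len)))
    pk_i <- which.max(avg)
    cross <- which(avg[seq_len(pk_i)] >= 0.1 * avg[pk_i])[1]
    latency_ms <- (w[1] + (cross - 1) / fs) * 1000
  }
  list(detected = detected, evoked_amp = amp, latency_ms = latency_ms,
       polarity = polarity, baseline_sd = sigma, threshold = threshold,
       n_consistent = n_consistent)
}

#' Screen every ordered pair in a session
#'
#' Runs [detectEvokedResponse()] on each ordered (pre, post) pair of every
#' `ap_train` sweep set: with `n` simultaneously recorded cells this is
#' `n * (n - 1)` directed tests.
#'
#' @param session a [Session-class] containing `ap_train` sweep sets.
#' @inheritParams detectEvokedResponse
#' @return data.frame with one row per ordered test: `pre_id`, `post_id`,
#'   `pre_label`, `post_label`, `region`, `n_trials`, `detected`,
#'   `evoked_amp`, `latency_ms`, `baseline_sd`, `distance_um`.
#' @export
screenSession <- function(session, window_ms = c(1, 20), k_sd = NULL,
                          alpha = 0.01) {
  stopifnot(is(session, "Session"))
  sets <- Filter(function(s) s@protocol == "ap_train", session@sweepSets)
  if (!length(sets)) stop("session has no ap_train sweep sets")
  cl <- session@cells
  rows <- list()
  for (ss in sets) {
    pre <- ss@metadata$pre_id
    ap_times <- ss@metadata$ap_times
    ids <- names(ss@trials[[1]])
    avg <- lapply(ids, function(id)
      averageTrials(lapply(ss@trials, `[[`, id)))
    names(avg) <- ids
    for (post in setdiff(ids, pre)) {
      det <- detectEvokedResponse(avg[[post]], ap_times,
                                  window_ms = window_ms, k_sd = k_sd,
                                  alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = pre, post_id = post,
        pre_label = cl$label[cl$cell_id == pre],
        post_label = cl$label[cl$cell_id == post],
        region = cl$region[cl$cell_id == post],
        n_trials = length(ss@trials),
        detected = det$detected, evoked_amp = det$evoked_amp,
        latency_ms = det$latency_ms, baseline_sd = det$baseline_sd,
        distance_um = intersomaticDistance(cl, pre, post),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
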