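#' Per-cell PSC statistics and the presynaptic-count estimator
#'
#' Summarizes a cell's detected events: spontaneous count and mean
#' amplitude, the mean of the largest 5% of spontaneous amplitudes
#' (`ceiling(0.05 * n)` events, at least one), the mean optogenetic (oPSC)
#' amplitude, their ratio, and the estimated number of connected
#' presynaptic sources.  Because spontaneous PSCs typically reflect single
#' presynaptic sources, the oPSC/sPSC mean-amplitude ratio estimates how
#' many sources the light recruits; it is rounded to the nearest positive
#' integer (ratios below 0.5 still report 1 when any oPSC was detected,
#' and 0 means no optogenetic response at all).
#'
#' @param events data.frame from [detectEvents()] / [classifyOpto()].
#' @param top_frac fraction for the top-amplitude comparison (default 5%).
#' @return one-row data.frame: `n_spsc`, `n_opsc`, `mean_spsc_pA`,
#'   `top5_mean_pA`, `mean_opsc_pA`, `ratio`, `est_presyn_count`,
#'   `mean_rise_ms`, `mean_decay_tau_ms`, `available`.  When no
#'   spontaneous events exist the amplitude fields are `NA` and
#'   `available` is `FALSE`.
#' @export
eventStats <- function(events, top_frac = 0.05) {
  sp <- events[events$kind == "spontaneous", , drop = FALSE]
  op <- events[events$kind == "optogenetic", , drop = FALSE]
  n_sp <- nrow(sp); n_op <- nrow(op)
  if (n_sp == 0L)
    return(data.frame(n_spsc = 0L, n_opsc = n_op, mean_spsc_pA = NA_real_,
                      top5_mean_pA = NA_real_, mean_opsc_pA = NA_real_,
                      ratio = NA_real_, est_presyn_count = NA_integer_,
                      mean_rise_ms = NA_real_, mean_decay_tau_ms = NA_real_,
                      available = FALSE))
  if (n_sp < 20L)
    warning("fewer than 20 spontaneous events; top-", 100 * top_frac,
            "% estimate is unreliable")
  amps <- sp$peak_amp_pA
  k <- max(1L, ceiling(top_frac * n_sp))
  top5 <- mean(sort(amps, decreasing = TRUE)[seq_len(k)])
  mean_sp <- mean(amps)
  mean_op <- if (n_op) mean(op$peak_amp_pA) else NA_real_
  ratio <- if (n_op) mean_op / mean_sp else NA_real_
  est <- if (n_op == 0L) 0L else max(1L, as.integer(floor(ratio + 0.5)))
  data.frame(n_spsc = n_sp, n_opsc = n_op, mean_spsc_pA = mean_sp,
             top5_mean_pA = top5, mean_opsc_pA = mean_op, ratio = ratio,
             est_presyn_count = est,
             mean_rise_ms = mean(sp$rise_ms, na.rm = TRUE),
             mean_decay_tau_ms = mean(sp$decay_tau_ms, na.rm = TRUE),
             available = TRUE)
}

#' Histogram of per-cell oPSC/sPSC amplitude ratios
#'
#' Bins the ratio across cells (half-open bins `[lo, hi)`) and reports the
#' group mean and sd -- the summary underlying the "how many presynaptic
#' sources explain the optogenetic response" reading.
#'
#' @param stats data.frame of per-cell rows from [eventStats()]
#'   (rbind-ed), or any data.frame with a `ratio` column.
#' @param bin_width ratio bin width.
#' @return list: `breaks`, `counts`, `mean`, `sd`, `n`.
#' @export
ratioHistogram <- function(stats, bin_width = 0.5) {
  r <- stats$ratio
  r <- r[is.finite(r)]
  if (!length(r)) stop("no cells with a defined oPSC/sPSC ratio")
  bins <- floor(r / bin_width)
  lo <- seq(0, max(bins)) * bin_width
  counts <- tabulate(bins + 1L, nbins = length(lo))
  list(breaks = c(lo, max(lo) + bin_width), counts = counts,
       mean = mean(r), sd = stats::sd(r), n = length(r))
}
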