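#' Unit-peak synaptic kernel (difference of exponentials)
#'
#' The minimal kinetic model used for every simulated PSP/PSC:
#' `g(t) = (exp(-t/tau_d) - exp(-t/tau_r))`, scaled so its peak is exactly
#' 1, hence "amplitude" always means peak deviation.
#'
#' @param t_s time from event onset, s (values `< 0` give 0).
#' @param rise_ms,decay_ms rise and decay time constants, ms
#'   (`0 < rise < decay`).
#' @return numeric vector of kernel values, peak 1.
#' @examples
#' max(pscKernel(seq(0, 0.05, 1e-4), 1.5, 8))  # 1
#' @export
pscKernel <- function(t_s, rise_ms, decay_ms) {
  stopifnot(rise_ms > 0, decay_ms > rise_ms)
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  pk <- exp(-tpk / td) - exp(-tpk / tr)
  out <- numeric(length(t_s))
  pos <- t_s >= 0
  out[pos] <- (exp(-t_s[pos] / td) - exp(-t_s[pos] / tr)) / pk
  out
}

#' Regular action-potential train times
#'
#' Times of an imposed presynaptic train: `n_spikes` spikes at `rate` Hz
#' starting at `start` (the screening protocol uses 5 spikes at 50 Hz).
#'
#' @param n_spikes number of spikes (`>= 1`).
#' @param rate train rate, Hz (`> 0`).
#' @param start time of the first spike, s.
#' @return numeric vector of spike times, s.
#' @examples
#' generateApTrain(5, 50, 0.1)  # 0.10 0.12 0.14 0.16 0.18
#' @export
generateApTrain <- function(n_spikes, rate, start = 0) {
  stopifnot(n_spikes >= 1, rate > 0)
  start + (seq_len(n_spikes) - 1) / rate
}

## stereotyped AP waveform added on top of the membrane potential:
## 0.5 ms depolarizing ramp to ~+45 mV above baseline, 0.7 ms repolarization,
## brief afterhyperpolarization.  Returns the additive waveform (mV).
apWaveform <- function(sampling_rate) {
  dt <- 1 / sampling_rate
  t <- seq(0, 0.004, by = dt)
  up <- pmin(t / 5e-4, 1)
  down <- exp(-pmax(t - 5e-4, 0) / 3e-4)
  ahp <- -8 * pmax(t - 8e-4, 0) / 1.2e-3 * exp(-pmax(t - 8e-4, 0) / 1.2e-3)
  85 * up * down + ahp
}

#' Simulate a single-compartment membrane response
#'
#' Leaky RC membrane with threshold-reset spiking driven by an injected
#' current trace.  Subthreshold, the voltage obeys
#' `V = V_rest + I * R_m * (1 - exp(-t / tau))` with `tau = R_m * C_m`
#' (exact exponential-Euler update per sample).  Crossing `V_thresh`
#' triggers a stereotyped spike waveform, a reset to `V_reset` and an
#' absolute refractory period.
#'
#' @param config a [simConfig()] (fields `membrane`, `sampling_rate`).
#' @param input_current a [Trace-class] whose *samples* are the injected
#'   current in pA (clamp mode is ignored), or a plain numeric vector.
#' @param noise_sd additive Gaussian voltage noise sd, mV (default 0:
#'   deterministic).
#' @return a current-clamp [Trace-class] (mV) with the input as stimulus
#'   channel and spike times (s) in `attr(, "spike_times")`.
#' @examples
#' cfg <- simConfig()
#' i <- c(rep(0, 100), rep(-30, 2000), rep(0, 400))
#' v <- simulateMembrane(cfg, i)   # steady deflection -6 mV at 200 MOhm
#' @export
simulateMembrane <- function(config, input_current, noise_sd = 0) {
  m <- config$membrane
  fs <- config$sampling_rate
  I <- if (is(input_current, "Trace")) input_current@samples
       else as.numeric(input_current)
  if (!all(is.finite(c(m$R_m, m$C_m, m$V_rest, m$V_thresh, m$V_reset))))
    stop("membrane configuration contains non-finite parameters")
  dt <- 1 / fs
  tau <- m$R_m * m$C_m * 1e-6            # MOhm * pF -> s
  a <- exp(-dt / tau)
  n <- length(I)
  v <- numeric(n)
  v[1] <- m$V_rest
  refrac_n <- max(1L, round(m$refrac_ms / 1000 * fs))
  spike_at <- integer(0)
  hold <- 0L
  for (k in seq_len(n - 1L)) {
    if (hold > 0L) {
      v[k + 1L] <- m$V_reset
      hold <- hold - 1L
      next
    }
    vinf <- m$V_rest + I[k] * m$R_m * 1e-3   # pA * MOhm -> mV (x 1e-3)
    v[k + 1L] <- vinf + (v[k] - vinf) * a
    if (v[k + 1L] >= m$V_thresh) {
      spike_at <- c(spike_at, k + 1L)
      v[k + 1L] <- m$V_reset
      hold <- refrac_n
    }
  }
  ## render spikes as stereotyped waveforms on top of the trace
  if (length(spike_at)) {
    wf <- apWaveform(fs)
    for (s in spike_at) {
      idx <- s:min(n, s + length(wf) - 1L)
      v[idx] <- v[idx] + wf[seq_along(idx)]
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  out <- Trace(v, samplingRate = fs, clampMode = "current_clamp",
               stimulus = I)
  attr(out, "spike_times") <- (spike_at - 1L) / fs
  out
}
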