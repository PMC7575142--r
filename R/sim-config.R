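#' Simulation configuration
#'
#' Builds the parameter set for the slice-electrophysiology simulator.
#' Defaults emulate the experimental designs under study: quadruple
#' whole-cell configurations probed with 5-spike 50 Hz trains, sparse
#' chemical/electrical connectivity at the screened rates, spontaneous PSC
#' barrages with a right-skewed (log-normal) amplitude law on the 20.3 pA
#' scale, light-pulse evoked PSCs with few-ms latencies, and 5 s linear
#' light ramps that either do (cortex-like) or do not (hypothalamus-like)
#' recruit a 10-80 Hz synaptic oscillation.
#'
#' @param preset `"lh"` (ultra-sparse connectivity, no ramp oscillation) or
#'   `"mpfc"` (dense connectivity, ramp oscillation).  Individual arguments
#'   override preset values.
#' @param n_cells simultaneously recorded cells (default 4, a quadruple).
#' @param p_chem probability of each directed chemical connection.
#' @param p_elec probability of electrical coupling per (unordered) pair.
#' @param psp_amp evoked PSP amplitude, mV (current clamp).
#' @param psc_amp evoked PSC amplitude, pA (voltage clamp).
#' @param psp_rise_ms,psp_decay_ms kinetics of the difference-of-exponentials
#'   synaptic kernel (20-80% style rise / decay time constants), ms.
#' @param noise_sd_mv,noise_sd_pa additive Gaussian recording noise sd in
#'   current clamp (mV) and voltage clamp (pA).
#' @param spsc_rate spontaneous PSC rate, Hz.  The source study does not
#'   report sPSC frequency; this is a free parameter of the generator.
#' @param spsc_amp_med median of the log-normal sPSC amplitude law, pA.
#' @param spsc_amp_sigma log-sd of the sPSC amplitude law.
#' @param opto list: `pop_size` (opsin+ population size), `n_connected`
#'   (how many are presynaptic to the recorded cell), `latency_mean_ms`,
#'   `latency_jitter_ms`, `p_multiplet` (probability a source fires a
#'   second spike 3-8 ms later, yielding a compound multiphasic oPSC).
#' @param ramp list: `duration_s` (default 5), `oscillatory`, `osc_band`
#'   (Hz pair), `osc_freq` (carrier frequency within the band, Hz),
#'   `osc_amp_pa` (oscillation envelope at full light intensity, pA),
#'   `tonic_amp_pa` (slow inward current at full intensity, pA),
#'   `baseline_s` (pre-ramp segment, default 1.5 s).
#' @param membrane list: `R_m` (MOhm), `C_m` (pF), `V_rest` (mV),
#'   `V_thresh`, `V_reset` (mV), `refrac_ms`.
#' @param sampling_rate Hz (at least 10 kHz, matching the acquisition
#'   regime being emulated).
#' @param seed integer; fully determines all generator output.  Each
#'   simulator stage draws from its own substream derived from this seed
#'   by a fixed offset, so stages are reproducible independently.
#' @return a validated object of class `"SimConfig"` (a named list).
#' @examples
#' cfg <- simConfig(preset = "lh", seed = 1)
#' cfg$p_chem
#' @export
simConfig <- function(preset = c("lh", "mpfc"),
                      n_cells = 4,
                      p_chem = NULL,
                      p_elec = NULL,
                      psp_amp = 0.5,
                      psc_amp = 20.3,
                      psp_rise_ms = 1.5,
                      psp_decay_ms = 8,
                      noise_sd_mv = 0.1,
                      noise_sd_pa = 2,
                      spsc_rate = 2,
                      spsc_amp_med = 20.3,
                      spsc_amp_sigma = 0.6,
                      opto = list(),
                      ramp = list(),
                      membrane = list(),
                      sampling_rate = 10000,
                      seed = 1L) {
  preset <- match.arg(preset)
  ## screened connection rates: 1/2074 directed chemical and 3/1037 coupled
  ## pairs in the LH; 43/362 and 3/181 in the mPFC benchmark
  if (is.null(p_chem)) p_chem <- if (preset == "lh") 1 / 2074 else 43 / 362
  if (is.null(p_elec)) p_elec <- if (preset == "lh") 3 / 1037 else 3 / 181
  opto_def <- list(pop_size = 1000L, n_connected = 1L,
                   latency_mean_ms = 6, latency_jitter_ms = 1,
                   p_multiplet = 0.1)
  ramp_def <- list(duration_s = 5, oscillatory = (preset == "mpfc"),
                   osc_band = c(10, 80), osc_freq = 40, osc_amp_pa = 20,
                   tonic_amp_pa = 30, baseline_s = 1.5)
  memb_def <- list(R_m = 200, C_m = 100, V_rest = -60, V_thresh = -40,
                   V_reset = -50, refrac_ms = 3)
  opto <- utils::modifyList(opto_def, opto)
  ramp <- utils::modifyList(ramp_def, ramp)
  membrane <- utils::modifyList(memb_def, membrane)

  cfg <- list(preset = preset, n_cells = as.integer(n_cells),
              p_chem = p_chem, p_elec = p_elec, psp_amp = psp_amp,
              psc_amp = psc_amp, psp_rise_ms = psp_rise_ms,
              psp_decay_ms = psp_decay_ms, noise_sd_mv = noise_sd_mv,
              noise_sd_pa = noise_sd_pa, spsc_rate = spsc_rate,
              spsc_amp_med = spsc_amp_med, spsc_amp_sigma = spsc_amp_sigma,
              opto = opto, ramp = ramp, membrane = membrane,
              sampling_rate = sampling_rate, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid SimConfig: ", what,
                                          call. = FALSE)
  chk(cfg$n_cells >= 1, "n_cells must be >= 1")
  chk(cfg$p_chem >= 0 && cfg$p_chem <= 1, "p_chem must lie in [0, 1]")
  chk(cfg$p_elec >= 0 && cfg$p_elec <= 1, "p_elec must lie in [0, 1]")
  chk(cfg$psp_rise_ms > 0 && cfg$psp_decay_ms > cfg$psp_rise_ms,
      "kernel time constants must satisfy 0 < rise < decay")
  chk(cfg$noise_sd_mv >= 0 && cfg$noise_sd_pa >= 0, "noise sd must be >= 0")
  chk(cfg$spsc_rate >= 0, "spsc_rate must be >= 0")
  chk(cfg$spsc_amp_med > 0 && cfg$spsc_amp_sigma >= 0,
      "sPSC amplitude law needs positive median and non-negative log-sd")
  chk(cfg$opto$n_connected <= cfg$opto$pop_size,
      "opto$n_connected must not exceed opto$pop_size")
  chk(cfg$opto$p_multiplet >= 0 && cfg$opto$p_multiplet <= 1,
      "opto$p_multiplet must lie in [0, 1]")
  chk(cfg$ramp$duration_s > 0, "ramp$duration_s must be > 0")
  chk(cfg$sampling_rate >= 10000, "sampling_rate must be >= 10 kHz")
  for (p in c("R_m", "C_m")) chk(is.finite(cfg$membrane[[p]]) &&
                                 cfg$membrane[[p]] > 0,
                                 paste("membrane$", p, " must be > 0"))
  chk(is.finite(cfg$membrane$V_rest) && is.finite(cfg$membrane$V_thresh) &&
      is.finite(cfg$membrane$V_reset), "membrane potentials must be finite")
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed must be scalar")
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig [%s]: %d cells, p_chem = %.4g, p_elec = %.4g, seed = %d\n",
    x$preset, x$n_cells, x$p_chem, x$p_elec, x$seed))
  cat(sprintf("  sPSC: %.3g Hz, log-normal(median %.3g pA, sigma %.2g)\n",
              x$spsc_rate, x$spsc_amp_med, x$spsc_amp_sigma))
  cat(sprintf("  opto: %d/%d connected, latency %.3g +/- %.3g ms\n",
              x$opto$n_connected, x$opto$pop_size, x$opto$latency_mean_ms,
              x$opto$latency_jitter_ms))
  cat(sprintf("  ramp: %g s, oscillatory = %s (%g Hz, %g pA)\n",
              x$ramp$duration_s, x$ramp$oscillatory, x$ramp$osc_freq,
              x$ramp$osc_amp_pa))
  invisible(x)
}

## fixed substream offsets (one global seed, per-component streams)
.SUBSTREAM <- c(connection = 11L, coupling = 23L, spsc = 37L, opto = 53L,
                ramp = 71L, cells = 89L)

substreamSeed <- function(cfg, component) {
  off <- .SUBSTREAM[[component]]
  ## keep within 32-bit integer range
  as.integer((as.numeric(cfg$seed) * 97L + off) %% .Machine$integer.max)
}
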