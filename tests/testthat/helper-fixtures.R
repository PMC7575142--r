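## Shared fixtures, built in code at test time.

## a small quadruple-recording config with fast-to-simulate sessions
quickConfig <- function(seed = 1, ...) {
  simConfig(preset = "lh", seed = seed, ...)
}

## construct a trial-averaged trace with PSPs injected at known times,
## bypassing the session machinery (for detector-level tests)
makeMeanTrace <- function(amp, ap_times = generateApTrain(5, 50, 0.1),
                          noise_sd = 0.05 / sqrt(10), fs = 10000,
                          dur = 0.45, rise_ms = 1.5, decay_ms = 8,
                          delay_s = 0.0015, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (tt in ap_times)
    x <- x + amp * pscKernel(t - tt - delay_s, rise_ms, decay_ms)
  Trace(x + rnorm(length(t), 0, noise_sd), samplingRate = fs)
}

## voltage-clamp trace with inward PSCs injected at known times
makePscTrace <- function(times, amps, dur = 10, fs = 10000, noise_sd = 2,
                         rise_ms = 1.5, decay_ms = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_along(times))
    x <- x - amps[i] * pscKernel(t - times[i], rise_ms, decay_ms)
  Trace(x + rnorm(length(t), 0, noise_sd), samplingRate = fs,
        clampMode = "voltage_clamp")
}

## 10%-of-peak crossing time of the synaptic kernel (fine-grid oracle)
kernelOnset10 <- function(rise_ms, decay_ms) {
  tf <- seq(0, 0.05, by = 1e-6)
  zf <- pscKernel(tf, rise_ms, decay_ms)
  tf[min(which(zf >= 0.1 * max(zf)))]
}
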