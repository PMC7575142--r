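test_that("injected PSCs are recovered in count and amplitude", {
  times <- seq(0.5, 9.5, by = 1)
  tr <- makePscTrace(times, rep(20, 10), dur = 10, noise_sd = 2, seed = 51)
  ev <- detectEvents(tr, polarity = "inward")
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$peak_amp_pA - 20) / 20 <= 0.1))
  expect_true(all(abs(ev$onset_s - times) < 0.002))
})

test_that("a noiseless event is measured exactly", {
  tr <- makePscTrace(0.2, 20, dur = 1, noise_sd = 0)
  ev <- detectEvents(tr, polarity = "inward")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_amp_pA, 20, tolerance = 1e-4)
  ## onset follows the 10%-of-peak convention (within the smoothing width)
  expect_lt(abs(ev$onset_s - (0.2 + kernelOnset10(1.5, 8))), 3e-4)
  expect_equal(ev$decay_tau_ms, 8, tolerance = 0.02)
  expect_false(ev$compound)
})

test_that("pure noise yields few false events", {
  set.seed(52)
  tr <- Trace(rnorm(1e6, 0, 2), samplingRate = 10000,
              clampMode = "voltage_clamp")   # 100 s of noise
  ev <- detectEvents(tr, polarity = "inward")
  expect_lte(nrow(ev), 5)    # well under 0.05 events per second
})

test_that("polarity must be stated and is honoured", {
  tr <- makePscTrace(0.2, 20, dur = 1, noise_sd = 0)
  expect_error(detectEvents(tr), "polarity")
  ## an inward event is invisible to an outward-polarity search
  ev_out <- detectEvents(tr, polarity = "outward")
  expect_equal(nrow(ev_out), 0)
})

test_that("classification only sets kinds, never alters detections", {
  cfg <- quickConfig(seed = 53, opto = list(n_connected = 1))
  sw <- simulateOptoTrial(cfg, n_pulses = 10)
  tr <- trials(sw)[[1]][[1]]
  ev <- detectEvents(tr, polarity = "inward")
  ev2 <- classifyOpto(ev, sweepMetadata(sw)$light_times)
  ## the same detector serves both kinds: event set identical
  expect_equal(ev2$onset_s, ev$onset_s)
  expect_equal(ev2$peak_amp_pA, ev$peak_amp_pA)
  expect_true(any(ev2$kind == "optogenetic"))
})

test_that("light windows assign kinds by onset latency", {
  ev <- data.frame(onset_s = c(1.007, 1.5, 2.0), peak_s = c(1.01, 1.51, 2.01),
                   peak_amp_pA = c(30, 20, 25), rise_ms = 1, decay_tau_ms = 8,
                   halfwidth_ms = 5, compound = FALSE, kind = "spontaneous",
                   criterion = 10)
  out <- classifyOpto(ev, light_times = c(1, 1.99))
  expect_equal(out$kind, c("optogenetic", "spontaneous", "optogenetic"))
  expect_equal(out$latency_ms[1], 7, tolerance = 1e-9)
  ## no lights: everything stays spontaneous
  expect_true(all(classifyOpto(ev, numeric(0))$kind == "spontaneous"))
  ## overlapping windows are refused
  expect_error(classifyOpto(ev, c(1, 1.005)), "overlap")
})

test_that("latency is onset minus light, in ms, and must be causal", {
  expect_equal(latencyMs(1.0025, 1.0), 2.5)
  expect_equal(latencyMs(2, 2), 0)
  expect_error(latencyMs(0.999, 1), "precedes")
})

test_that("simulated latencies are recovered on average", {
  cfg <- quickConfig(seed = 54, opto = list(n_connected = 1,
                                            p_multiplet = 0,
                                            latency_mean_ms = 6,
                                            latency_jitter_ms = 1))
  sw <- simulateOptoTrial(cfg, n_pulses = 40)
  ev <- classifyOpto(detectEvents(trials(sw)[[1]][[1]], "inward"),
                     sweepMetadata(sw)$light_times)
  lat <- ev$latency_ms[ev$kind == "optogenetic"]
  expect_gt(length(lat), 25)
  ## onset convention adds ~the kernel's 10%-rise offset to the latency
  offset <- kernelOnset10(1.5, 8) * 1000
  expect_equal(mean(lat), 6 + offset, tolerance = 0.8)
})

test_that("event statistics follow their definitions", {
  ev <- data.frame(peak_amp_pA = 1:100, kind = "spontaneous",
                   rise_ms = 1, decay_tau_ms = 8)
  st <- eventStats(ev)
  expect_equal(st$top5_mean_pA, 98)     # mean of the 5 largest of 100
  expect_equal(st$mean_spsc_pA, 50.5)
  expect_equal(st$est_presyn_count, 0)  # no oPSCs at all
  ## top-5% mean always dominates the overall mean
  set.seed(55)
  for (i in 1:10) {
    amps <- rlnorm(50, 3, 0.6)
    s <- eventStats(data.frame(peak_amp_pA = amps, kind = "spontaneous",
                               rise_ms = 1, decay_tau_ms = 8))
    expect_gte(s$top5_mean_pA, s$mean_spsc_pA)
  }
  ## ratio and rounding of the source-count estimate
  ev2 <- rbind(ev, data.frame(peak_amp_pA = rep(50.5 * 0.3, 4),
                              kind = "optogenetic", rise_ms = 1,
                              decay_tau_ms = 8))
  st2 <- eventStats(ev2)
  expect_equal(st2$ratio, 0.3)
  expect_equal(st2$est_presyn_count, 1)  # oPSCs present: at least one source
  ## no spontaneous events: stats unavailable
  st3 <- eventStats(ev2[ev2$kind == "optogenetic", ])
  expect_false(st3$available)
  expect_true(is.na(st3$ratio))
})

test_that("kinetics fits are shape-true and scale-invariant", {
  fs <- 20000
  t <- seq(0, 0.08, by = 1 / fs)
  snip <- c(numeric(100), 20 * pscKernel(t, 1.5, 10))
  kin <- fitKinetics(snip, fs, pre_samples = 100)
  expect_equal(kin[2], 10, tolerance = 0.01)   # decay tau, ms
  kin_scaled <- fitKinetics(5 * snip, fs, pre_samples = 100)
  expect_equal(kin, kin_scaled, tolerance = 1e-6)
  ## 20-80% rise against a fine-grid oracle
  tf <- seq(0, 0.02, by = 1e-6)
  zf <- pscKernel(tf, 1.5, 10)
  oracle <- (tf[min(which(zf >= 0.8))] - tf[min(which(zf >= 0.2))]) * 1000
  expect_equal(kin[1], oracle, tolerance = 0.05)
})

test_that("overlapping events merge as compound, separated ones split", {
  ## two events 3 ms apart: one compound event, kinetics withheld
  tr <- makePscTrace(c(0.3, 0.303), c(20, 20), dur = 1, noise_sd = 0)
  ev <- detectEvents(tr, polarity = "inward")
  expect_equal(nrow(ev), 1)
  expect_true(ev$compound)
  expect_true(is.na(ev$decay_tau_ms))
  ## compound amplitude is the full superposed peak, larger than either
  expect_gt(ev$peak_amp_pA, 25)
  ## 8 ms apart: two separate events
  tr2 <- makePscTrace(c(0.3, 0.308), c(20, 20), dur = 1, noise_sd = 0)
  expect_equal(nrow(detectEvents(tr2, polarity = "inward")), 2)
})

test_that("brief action-current artifacts are vetoed by half-width", {
  cfg <- quickConfig(seed = 56, opto = list(n_connected = 1))
  sw <- simulateOptoTrial(cfg, n_pulses = 10, spike_artifacts = TRUE)
  ev <- detectEvents(trials(sw)[[1]][[1]], polarity = "inward")
  ## nothing narrower than a credible PSC survives
  expect_true(all(ev$halfwidth_ms >= 1))
  ## the ~600 pA artifacts did not enter the event list
  expect_true(all(ev$peak_amp_pA < 400))
})

test_that("single-source optogenetic responses match sPSC scale", {
  cfg <- quickConfig(seed = 57, opto = list(n_connected = 1,
                                            p_multiplet = 0))
  sw <- simulateOptoTrial(cfg, n_pulses = 50, ipi_s = 0.5)
  ev <- classifyOpto(detectEvents(trials(sw)[[1]][[1]], "inward"),
                     sweepMetadata(sw)$light_times)
  st <- eventStats(ev)
  expect_equal(st$est_presyn_count, 1)
  expect_gt(st$ratio, 0.6); expect_lt(st$ratio, 1.5)
})

test_that("ratio histograms summarize per-cell source counts", {
  stats <- data.frame(ratio = c(1, 1.1, 0.9, 2, 2.2))
  h <- ratioHistogram(stats, bin_width = 0.5)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$mean, mean(stats$ratio))
  ## modal bins sit at the 1x and 2x source counts
  top2 <- order(h$counts, decreasing = TRUE)[1:2]
  expect_setequal(h$breaks[top2], c(1.0, 2.0))
  expect_error(ratioHistogram(data.frame(ratio = NA_real_)), "no cells")
})
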