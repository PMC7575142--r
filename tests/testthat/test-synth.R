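test_that("membrane model obeys the RC charging law", {
  cfg <- quickConfig()
  ## no drive: flat at rest
  v0 <- simulateMembrane(cfg, numeric(2000))
  expect_true(all(samples(v0) == cfg$membrane$V_rest))
  ## -30 pA into 200 MOhm settles at -6 mV below rest (Ohm's law)
  i <- c(rep(0, 500), rep(-30, 3000), rep(0, 500))
  v <- simulateMembrane(cfg, i)
  steady <- mean(samples(v)[3300:3490])
  expect_equal(steady - cfg$membrane$V_rest, -6, tolerance = 0.01)
  ## halfway through one time constant the deflection is 1 - e^-1 of final
  tau_n <- round(cfg$membrane$R_m * cfg$membrane$C_m * 1e-6 *
                 cfg$sampling_rate)
  at_tau <- samples(v)[500 + tau_n] - cfg$membrane$V_rest
  expect_equal(at_tau, -6 * (1 - exp(-1)), tolerance = 0.05)
})

test_that("spike count grows monotonically with step current", {
  cfg <- quickConfig()
  counts <- vapply(c(120, 160, 220, 300), function(a) {
    v <- simulateMembrane(cfg, c(rep(0, 500), rep(a, 5000)))
    length(attr(v, "spike_times"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])
})

test_that("action-potential trains have exact regular timing", {
  expect_equal(generateApTrain(5, 50, 0.1),
               c(0.100, 0.120, 0.140, 0.160, 0.180))
  expect_equal(generateApTrain(1, 7, 0.3), 0.3)
  expect_equal(generateApTrain(3, 10, 0), c(0, 0.1, 0.2))
  expect_error(generateApTrain(0, 50))
})

test_that("connection sessions carry consistent ground truth", {
  ## null network: no chemical edges anywhere
  ses0 <- simulateConnectionSession(quickConfig(seed = 21, p_chem = 0),
                                    n_trials = 5, trial_s = 0.3)
  expect_false(any(groundTruth(ses0)$chem))
  ## full network at 1 mV: every averaged postsynaptic trace shows 5
  ## time-locked PSPs of about the configured amplitude
  cfg1 <- quickConfig(seed = 22, p_chem = 1, psp_amp = 1)
  ses1 <- simulateConnectionSession(cfg1, n_trials = 30)
  ss <- sweepSets(ses1)[[1]]
  pre <- sweepMetadata(ss)$pre_id
  post <- setdiff(names(trials(ss)[[1]]), pre)[1]
  avg <- averageTrials(lapply(trials(ss), `[[`, post))
  x <- samples(avg)
  fs <- samplingRate(avg)
  for (ap in sweepMetadata(ss)$ap_times) {
    seg <- x[round((ap + 0.002) * fs):round((ap + 0.012) * fs)]
    expect_gt(max(seg) - median(x[1:900]), 0.8)  # locked PSP present
  }
  ## ordered-pair bookkeeping: 4 cells -> 12 directed probes
  expect_equal(nrow(screenSession(ses1)), 12)
})

test_that("spontaneous PSC generator matches its Poisson and amplitude laws", {
  cfg <- quickConfig(seed = 23, spsc_rate = 2)
  tr <- simulateSpontaneousPscs(cfg, 100)
  n <- length(attr(tr, "event_times"))
  expect_lt(abs(n - 200), 3 * sqrt(200))
  ## zero rate: pure noise, no events
  tr0 <- simulateSpontaneousPscs(quickConfig(seed = 24, spsc_rate = 0), 5)
  expect_length(attr(tr0, "event_times"), 0)
  expect_lt(sd(samples(tr0)), 1.5 * cfg$noise_sd_pa)
  ## amplitude law: sample median near the 20.3 pA scale at n ~ 1e4
  big <- simulateSpontaneousPscs(quickConfig(seed = 25, spsc_rate = 20), 500)
  amps <- attr(big, "event_amps")
  expect_gt(length(amps), 9000)
  expect_equal(median(amps), 20.3, tolerance = 0.03)
})

test_that("event rendering is linear (superposition)", {
  ## k simultaneous unit events equal k times the single event, noise-free
  n <- 5000; fs <- 10000
  one <- sparseconn:::renderEvents(0.1, 1, n, fs, 1.5, 8)
  three <- sparseconn:::renderEvents(rep(0.1, 3), rep(1, 3), n, fs, 1.5, 8)
  expect_equal(three, 3 * one, tolerance = 1e-12)
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- quickConfig(seed = 31)
  a <- simulateOptoTrial(cfg, n_pulses = 5)
  b <- simulateOptoTrial(cfg, n_pulses = 5)
  expect_identical(samples(trials(a)[[1]][[1]]), samples(trials(b)[[1]][[1]]))
  ra <- simulateRampSession(cfg, n_trials = 2)
  rb <- simulateRampSession(cfg, n_trials = 2)
  expect_identical(samples(trials(sweepSets(ra)[[1]])[[2]][[1]]),
                   samples(trials(sweepSets(rb)[[1]])[[2]][[1]]))
  ## and stage substreams do not disturb the caller's RNG
  set.seed(5); x1 <- rnorm(1)
  set.seed(5); invisible(simulateOptoTrial(cfg, n_pulses = 2))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("opto trials place evoked PSCs at configured latencies", {
  cfg <- quickConfig(seed = 32, opto = list(n_connected = 1,
                                            p_multiplet = 0))
  sw <- simulateOptoTrial(cfg, n_pulses = 20)
  gt <- sweepMetadata(sw)$ground_truth
  lat <- (gt$opto_times - rep(sweepMetadata(sw)$light_times,
                              each = 1)) * 1000
  expect_equal(mean(lat), cfg$opto$latency_mean_ms, tolerance = 0.2)
  expect_equal(length(gt$opto_times), 20)
  ## no connected sources: no evoked events at all
  sw0 <- simulateOptoTrial(quickConfig(seed = 33,
                                       opto = list(n_connected = 0)),
                           n_pulses = 10)
  expect_length(sweepMetadata(sw0)$ground_truth$opto_times, 0)
})

test_that("ramp sessions encode the light program in the stimulus channel", {
  ses <- simulateRampSession(quickConfig(seed = 34), n_trials = 1)
  tr <- trials(sweepSets(ses)[[1]])[[1]][[1]]
  li <- stimulus(tr)
  on <- sweepMetadata(sweepSets(ses)[[1]])$ramp_onset_s
  fs <- samplingRate(tr)
  expect_equal(li[round(on * fs) - 10], 0)
  expect_equal(li[round((on + 2.5) * fs)], 0.5, tolerance = 1e-3)
  expect_equal(max(li), 1, tolerance = 1e-3)
})
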