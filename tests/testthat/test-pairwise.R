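test_that("trial averaging is exact and reduces white noise as 1/sqrt(N)", {
  tr <- Trace(sin(seq_len(1000) / 50))
  expect_equal(samples(averageTrials(list(tr, tr, tr))), samples(tr))
  expect_equal(samples(averageTrials(list(tr))), samples(tr))
  expect_error(averageTrials(list(tr, Trace(rnorm(500)))), "mixed lengths")
  set.seed(41)
  noise <- lapply(1:50, function(i) Trace(rnorm(2000)))
  expect_equal(sd(samples(averageTrials(noise))), 1 / sqrt(50),
               tolerance = 0.15)
})

test_that("evoked-response detection recovers injected PSP amplitudes", {
  mt <- makeMeanTrace(0.5, noise_sd = 0.05, seed = 42)
  det <- detectEvokedResponse(mt, generateApTrain(5, 50, 0.1))
  expect_true(det$detected)
  expect_equal(det$evoked_amp, 0.5, tolerance = 0.1)
  expect_equal(det$polarity, 1)
  ## the literal fixed-factor rule also fires at this signal-to-noise
  det3 <- detectEvokedResponse(mt, generateApTrain(5, 50, 0.1), k_sd = 3)
  expect_true(det3$detected)
  ## latency to the 10%-of-peak crossing is a couple of ms
  expect_gt(det$latency_ms, 1)
  expect_lt(det$latency_ms, 4)
  ## too little baseline before the first spike is an error
  expect_error(
    detectEvokedResponse(mt, generateApTrain(5, 50, 0.03)), "50 ms")
})

test_that("null traces are rarely called connected at the nominal alpha", {
  set.seed(43)
  hits <- vapply(1:40, function(i) {
    mt <- makeMeanTrace(0, noise_sd = 0.0316)
    detectEvokedResponse(mt, generateApTrain(5, 50, 0.1))$detected
  }, logical(1))
  expect_lte(sum(hits), 3)   # alpha 0.01: 40 nulls should give ~0 hits
})

test_that("detection probability is monotone in PSP amplitude", {
  set.seed(44)
  prob <- vapply(c(0.05, 0.12, 0.3), function(a) {
    mean(vapply(1:40, function(i) {
      mt <- makeMeanTrace(a, noise_sd = 0.0316)
      detectEvokedResponse(mt, generateApTrain(5, 50, 0.1))$detected
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(prob) >= -0.05))
  expect_gt(prob[3], 0.95)
})

test_that("screening a session tests every ordered pair and finds edges", {
  ## strong edges (5x averaged-noise sd) are fully recovered
  cfg <- quickConfig(seed = 45, p_chem = 0.5,
                     psp_amp = 5 * 0.1 / sqrt(10))
  ses <- simulateConnectionSession(cfg, n_trials = 10)
  sc <- screenSession(ses)
  expect_equal(nrow(sc), 12)
  gt <- groundTruth(ses)$chem
  truth <- mapply(function(p, q) gt[p, q], sc$pre_id, sc$post_id)
  expect_true(all(sc$detected[truth]))
  ## null session: no detections expected at alpha 0.01
  ses0 <- simulateConnectionSession(quickConfig(seed = 46, p_chem = 0),
                                    n_trials = 10)
  expect_lte(sum(screenSession(ses0)$detected), 1)
})

test_that("coupling coefficient is the steady-state voltage ratio", {
  fs <- 10000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  step <- as.numeric(t >= 0.2 & t < 0.7)
  pre <- Trace(-50 - 10 * step, samplingRate = fs)
  post <- Trace(-50 - 0.75 * step, samplingRate = fs)
  expect_equal(couplingCoefficient(pre, post, c(0.2, 0.7)), 0.075)
  ## no transfer -> 0; identical trace -> 1
  expect_equal(couplingCoefficient(pre, Trace(rep(-50, fs)), c(0.2, 0.7)), 0)
  expect_equal(couplingCoefficient(pre, pre, c(0.2, 0.7)), 1)
  ## sub-millivolt presynaptic deflections are flagged, not ratioed
  weak <- Trace(-50 - 0.5 * step, samplingRate = fs)
  expect_warning(cc <- couplingCoefficient(weak, post, c(0.2, 0.7)),
                 "unreliable")
  expect_true(is.na(cc))
})

test_that("simulated coupling coefficients are recovered accurately", {
  cm <- matrix(0, 4, 4)
  cm[1, 2] <- cm[2, 1] <- 0.075
  cm[3, 4] <- cm[4, 3] <- 0.01
  ses <- simulateCouplingSession(quickConfig(seed = 47), n_trials = 5,
                                 coeff_matrix = cm)
  ct <- couplingTests(ses)
  r12 <- ct[ct$cell_a == "c1" & ct$cell_b == "c2", ]
  r34 <- ct[ct$cell_a == "c3" & ct$cell_b == "c4", ]
  expect_equal(r12$coeff_ab, 0.075, tolerance = 0.1)
  expect_equal(r34$coeff_ab, 0.01, tolerance = 0.1)
  expect_true(r12$bidirectional && r34$bidirectional)
  expect_false(any(ct$coupled[!(ct$cell_a %in% c("c1", "c3"))]))
})

test_that("rate tables reproduce screened-count arithmetic with exact CIs", {
  ## 1 synapse in 2,074 directed tests
  r <- rateFromCounts(1, 2074)
  expect_equal(r$rate, 4.8e-4, tolerance = 0.01)
  ## 0/50: zero rate but a 7.1% upper bound
  r0 <- rateFromCounts(0, 50)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_upper, 1 - 0.025^(1 / 50), tolerance = 1e-6)
  ## the cortical benchmark: 43/362
  expect_equal(rateFromCounts(43, 362)$rate, 0.119, tolerance = 0.01)
  ## CI always contains the point rate
  for (k in c(0, 1, 25, 50))
    with(rateFromCounts(k, 50), {
      expect_lte(ci_lower, rate); expect_gte(ci_upper, rate)
    })
})

test_that("rate tables conserve counts over groups", {
  cfg <- quickConfig(seed = 48, p_chem = 0.5, psp_amp = 0.5)
  sc <- screenSession(simulateConnectionSession(cfg, n_trials = 10))
  rt <- rateTable(sc, by = c("pre_label", "post_label"))
  expect_equal(sum(rt$n_tested), nrow(sc))
  expect_equal(sum(rt$n_connected), sum(sc$detected))
  ## directed tests are twice the simultaneously probed pairs
  expect_equal(nrow(sc), 2 * choose(4, 2))
})

test_that("distance histograms use half-open bins and compare groups", {
  tests <- data.frame(distance_um = c(10, 10, 10), detected = FALSE)
  h <- distanceHistogram(tests, bin_um = 25)
  expect_equal(sum(h$n_FALSE > 0), 1)
  ## a boundary value falls in the upper bin
  hb <- distanceHistogram(data.frame(distance_um = 25, detected = FALSE),
                          bin_um = 25)
  expect_equal(hb$n_FALSE[hb$bin_lo == 25], 1)
  ## region contrast: LH distances ran longer than mPFC distances
  set.seed(49)
  d_lh <- pmax(rnorm(400, 71.6, 65.7), 3)
  d_mp <- pmax(rnorm(400, 50.3, 32.4), 4.4)
  tests2 <- data.frame(distance_um = c(d_lh, d_mp),
                       region = rep(c("LH", "mPFC"), each = 400))
  h2 <- distanceHistogram(tests2, bin_um = 25, group = "region")
  expect_lt(attr(h2, "ranksum")$p, 0.01)
})
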