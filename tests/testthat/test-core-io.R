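test_that("Trace enforces its invariants", {
  expect_error(Trace(1:10, samplingRate = -1), "samplingRate")
  expect_error(Trace(1:10, stimulus = 1:5), "stimulus")
  tr <- Trace(rnorm(100), samplingRate = 20000,
              clampMode = "voltage_clamp", t0 = 1)
  expect_equal(traceUnits(tr), "pA")
  expect_equal(traceTimes(tr)[1], 1)
  expect_equal(diff(traceTimes(tr))[1], 5e-5)
})

test_that("session round-trip preserves every field to full precision", {
  cfg <- quickConfig(seed = 11, p_chem = 1)
  ses <- simulateConnectionSession(cfg, n_trials = 3, trial_s = 0.3)
  path <- tempfile(fileext = ".rds")
  writeSession(ses, path)
  back <- readSession(path)
  expect_identical(cells(back), cells(ses))
  expect_identical(groundTruth(back)$chem, groundTruth(ses)$chem)
  expect_identical(
    samples(trials(sweepSets(back)[[2]])[[1]][["c3"]]),
    samples(trials(sweepSets(ses)[[2]])[[1]][["c3"]]))
  expect_identical(sweepMetadata(sweepSets(back)[[1]]),
                   sweepMetadata(sweepSets(ses)[[1]]))
  unlink(path)
})

test_that("malformed containers fail with a field-naming error", {
  path <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), path)
  expect_error(readSession(path), "format")
  ## mismatched simultaneous trace lengths inside a trial group
  enc <- list(
    format = "sparseconn-session", version = 1L,
    cells = cellTable(c("a", "b"), x_um = c(0, 1), y_um = c(0, 1)),
    sweeps = list(list(
      protocol = "spontaneous", metadata = list(),
      trials = list(list(
        a = list(samples = rnorm(100), sampling_rate = 10000,
                 clamp_mode = "current_clamp", t0 = 0, stimulus = numeric()),
        b = list(samples = rnorm(50), sampling_rate = 10000,
                 clamp_mode = "current_clamp", t0 = 0,
                 stimulus = numeric()))))),
    ground_truth = list())
  saveRDS(enc, path)
  expect_error(readSession(path), "mismatched lengths")
  unlink(path)
})

test_that("a 4-cell session with many trials recovers all traces", {
  cfg <- quickConfig(seed = 12)
  ses <- simulateConnectionSession(cfg, n_trials = 50, trial_s = 0.3)
  path <- tempfile(fileext = ".rds")
  writeSession(ses, path)
  back <- readSession(path)
  ap <- Filter(function(s) protocol(s) == "ap_train", sweepSets(back))
  expect_length(ap, 4)
  n_traces <- sum(vapply(ap, function(s)
    sum(lengths(trials(s))), integer(1)))
  expect_equal(n_traces, 4 * 50 * 4)   # 4 driven cells x 50 trials x 4 cells
  unlink(path)
})

test_that("intersomatic distance follows plane geometry", {
  cl <- cellTable(c("a", "b", "o"), x_um = c(0, 3, NA),
                  y_um = c(0, 4, NA))
  expect_equal(intersomaticDistance(cl, "a", "b"), 5)
  expect_equal(intersomaticDistance(cl, "a", "a"), 0)
  ## unavailable coordinates give NA, never 0
  expect_true(is.na(intersomaticDistance(cl, "a", "o")))
  expect_error(intersomaticDistance(cl, "a", "zz"), "not found")
  ## the closest pair screened in the hypothalamus was 3.0 um apart
  near <- cellTable(c("p", "q"), x_um = c(0, 3), y_um = c(0, 0))
  expect_equal(intersomaticDistance(near, "p", "q"), 3.0)
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  set.seed(99)
  for (rep in 1:20) {
    cl <- cellTable(c("a", "b", "c"), x_um = rnorm(3, 0, 50),
                    y_um = rnorm(3, 0, 50))
    dab <- intersomaticDistance(cl, "a", "b")
    dba <- intersomaticDistance(cl, "b", "a")
    dbc <- intersomaticDistance(cl, "b", "c")
    dac <- intersomaticDistance(cl, "a", "c")
    expect_identical(dab, dba)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("session validity catches inconsistent structures", {
  cl <- cellTable(c("a", "b"), x_um = c(0, 1), y_um = c(0, 1))
  tr <- list(list(zz = Trace(rnorm(10))))
  ss <- ProtocolSweepSet("spontaneous", tr)
  expect_error(Session(cl, list(ss)), "unknown cell_id")
  expect_error(Session(cl, groundTruth = list(chem = matrix(FALSE, 3, 3))),
               "square over cells")
  expect_error(cellTable("a", depth_um = -5) |> Session(),
               "depth_um")
})
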