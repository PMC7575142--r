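## Session-level simulators.  Every generator draws from a substream
## derived from config$seed by a fixed offset (see substreamSeed), so a
## given SimConfig always produces identical output, and the caller's RNG
## state is never touched.

## helper: simulated cell table with somata scattered so that pairwise
## distances match the screened regimes (mean ~72 um LH, ~50 um mPFC)
simCells <- function(cfg, region = c("LH", "mPFC"), opsin_positive = FALSE) {
  region <- match.arg(region)
  n <- cfg$n_cells
  ## per-coordinate Gaussian scatter sd s gives mean pairwise distance
  ## s * sqrt(pi); invert for the target regional mean
  target <- if (region == "LH") 71.6 else 50.3
  s <- target / sqrt(pi)
  depth <- pmin(pmax(stats::rnorm(n, 37.2, 22.5), 12), 123)
  cellTable(sprintf("c%d", seq_len(n)), label = "n.m.", region = region,
            x_um = stats::rnorm(n, 0, s), y_um = stats::rnorm(n, 0, s),
            depth_um = depth, opsin_positive = opsin_positive)
}

## helper: Poisson sPSC event draw (times in [0, duration), log-normal amps)
drawSpscEvents <- function(cfg, duration) {
  n <- stats::rpois(1, cfg$spsc_rate * duration)
  list(times = sort(stats::runif(n, 0, duration)),
       amps = stats::rlnorm(n, meanlog = log(cfg$spsc_amp_med),
                            sdlog = cfg$spsc_amp_sigma))
}

## helper: render events (onset times s, peak amplitudes, sign) into a
## sampled current/voltage deflection vector of n samples
renderEvents <- function(times, amps, n, fs, rise_ms, decay_ms, sgn = -1) {
  out <- numeric(n)
  if (!length(times)) return(out)
  klen <- min(n, ceiling((6 * decay_ms / 1000) * fs))
  kern <- pscKernel(seq(0, by = 1 / fs, length.out = klen), rise_ms, decay_ms)
  for (i in seq_along(times)) {
    i0 <- floor(times[i] * fs) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + klen - 1L)
    out[idx] <- out[idx] + sgn * amps[i] * kern[seq_along(idx)]
  }
  out
}

#' Simulate a multi-cell connection-screening session
#'
#' Emulates the quadruple-recording screen: each cell in turn is driven
#' with a 5-spike 50 Hz action-potential train while the other cells'
#' membrane potentials are recorded.  Directed chemical connections are
#' drawn with probability `p_chem`; connected pairs produce PSPs
#' time-locked to each presynaptic spike (amplitude `psp_amp`, the
#' difference-of-exponentials kinetics, 1.5 ms synaptic delay) on top of
#' Gaussian noise of sd `noise_sd_mv`.  The generative connectivity is
#' stored in `groundTruth`.
#'
#' @param config a [simConfig()].
#' @param n_trials trials per driven cell (the screening protocol averages
#'   30-50).
#' @param trial_s trial duration, s.
#' @param train_start time of the first imposed spike, s (leaves a
#'   baseline segment for the detector).
#' @return a [Session-class] with one `ap_train` sweep set per driven cell
#'   and ground-truth matrices `chem`, `chem_amp`, `elec`.
#' @export
simulateConnectionSession <- function(config, n_trials = 30, trial_s = 0.45,
                                      train_start = 0.1) {
  validateSimConfig(config)
  withLocalSeed(substreamSeed(config, "connection"), {
    cfg <- config
    n <- cfg$n_cells
    fs <- cfg$sampling_rate
    cl <- withLocalSeed(substreamSeed(cfg, "cells"),
                        simCells(cfg, if (cfg$preset == "lh") "LH" else "mPFC"))
    ids <- cl$cell_id
    chem <- matrix(stats::runif(n * n) < cfg$p_chem, n, n,
                   dimnames = list(ids, ids))
    diag(chem) <- FALSE
    chem_amp <- matrix(0, n, n, dimnames = list(ids, ids))
    chem_amp[chem] <- cfg$psp_amp
    elec <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j &&
        stats::runif(1) < cfg$p_elec)
      elec[i, j] <- elec[j, i] <- stats::runif(1, 0.02, 0.13)

    ap_times <- generateApTrain(5, 50, train_start)
    ns <- round(trial_s * fs)
    tgrid <- (seq_len(ns) - 1) / fs
    v_hold <- -50                       # holding potential, mV
    delay_s <- 0.0015                   # synaptic delay
    wf <- apWaveform(fs)

    pre_wave <- numeric(ns)             # driven cell: stereotyped spikes
    for (tt in ap_times) {
      i0 <- round(tt * fs) + 1L
      idx <- i0:min(ns, i0 + length(wf) - 1L)
      pre_wave[idx] <- pre_wave[idx] + wf[seq_along(idx)]
    }
    psp_wave <- renderEvents(ap_times + delay_s, rep(1, length(ap_times)),
                             ns, fs, cfg$psp_rise_ms, cfg$psp_decay_ms,
                             sgn = +1)

    sweeps <- lapply(seq_len(n), function(pre) {
      tr <- lapply(seq_len(n_trials), function(trial) {
        grp <- lapply(seq_len(n), function(post) {
          base <- if (post == pre) v_hold + pre_wave
                  else v_hold + chem_amp[pre, post] * psp_wave
          Trace(base + stats::rnorm(ns, 0, cfg$noise_sd_mv),
                samplingRate = fs, clampMode = "current_clamp")
        })
        names(grp) <- ids
        grp
      })
      new("ProtocolSweepSet", protocol = "ap_train", trials = tr,
          metadata = list(pre_id = ids[pre], ap_times = ap_times,
                          n_spikes = 5L, train_rate_hz = 50))
    })
    Session(cl, sweeps,
            groundTruth = list(chem = chem, chem_amp = chem_amp, elec = elec))
  })
}

#' Simulate a coupling-test (current-step) session
#'
#' Each cell in turn receives a hyperpolarizing current step while all
#' cells are recorded in current clamp.  Electrically coupled pairs (drawn
#' with probability `p_elec`, or imposed via `coeff_matrix`) transfer the
#' steady-state voltage deflection scaled by the coupling coefficient.
#'
#' @param config a [simConfig()].
#' @param n_trials trials per stepped cell.
#' @param step_pa step amplitude, pA (negative = hyperpolarizing).
#' @param step_window step onset/offset, s.
#' @param trial_s trial duration, s.
#' @param coeff_matrix optional symmetric matrix of imposed coupling
#'   coefficients (overrides the random draw).
#' @return a [Session-class] with one `current_step` sweep set per stepped
#'   cell and ground-truth `elec` matrix.
#' @export
simulateCouplingSession <- function(config, n_trials = 5, step_pa = -50,
                                    step_window = c(0.2, 0.7),
                                    trial_s = 1.0, coeff_matrix = NULL) {
  validateSimConfig(config)
  withLocalSeed(substreamSeed(config, "coupling"), {
    cfg <- config
    n <- cfg$n_cells
    fs <- cfg$sampling_rate
    cl <- withLocalSeed(substreamSeed(cfg, "cells"),
                        simCells(cfg, if (cfg$preset == "lh") "LH" else "mPFC"))
    ids <- cl$cell_id
    if (is.null(coeff_matrix)) {
      elec <- matrix(0, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j &&
          stats::runif(1) < cfg$p_elec)
        elec[i, j] <- elec[j, i] <- stats::runif(1, 0.02, 0.13)
    } else {
      elec <- coeff_matrix
      dimnames(elec) <- list(ids, ids)
    }
    ns <- round(trial_s * fs)
    tgrid <- (seq_len(ns) - 1) / fs
    v_hold <- -50
    tau <- cfg$membrane$R_m * cfg$membrane$C_m * 1e-6
    dv <- step_pa * cfg$membrane$R_m * 1e-3     # steady-state deflection, mV
    on <- tgrid >= step_window[1] & tgrid < step_window[2]
    deflect <- numeric(ns)
    deflect[on] <- dv * (1 - exp(-(tgrid[on] - step_window[1]) / tau))
    after <- tgrid >= step_window[2]
    deflect[after] <- dv * (1 - exp(-(step_window[2] - step_window[1]) / tau)) *
      exp(-(tgrid[after] - step_window[2]) / tau)

    sweeps <- lapply(seq_len(n), function(pre) {
      stim <- numeric(ns); stim[on] <- step_pa
      tr <- lapply(seq_len(n_trials), function(trial) {
        grp <- lapply(seq_len(n), function(post) {
          g <- if (post == pre) 1 else elec[pre, post]
          Trace(v_hold + g * deflect + stats::rnorm(ns, 0, cfg$noise_sd_mv),
                samplingRate = fs, clampMode = "current_clamp",
                stimulus = if (post == pre) stim else numeric())
        })
        names(grp) <- ids
        grp
      })
      new("ProtocolSweepSet", protocol = "current_step", trials = tr,
          metadata = list(pre_id = ids[pre], step_window = step_window,
                          step_pa = step_pa))
    })
    Session(cl, sweeps, groundTruth = list(elec = elec))
  })
}

#' Simulate a spontaneous PSC recording
#'
#' Voltage-clamp trace of Poisson spontaneous PSCs: event times at
#' `spsc_rate` Hz, each a difference-of-exponentials inward current whose
#' peak amplitude is drawn from the log-normal law
#' (median `spsc_amp_med`, log-sd `spsc_amp_sigma`), plus Gaussian noise.
#' Injected event times and amplitudes are stored as ground truth in
#' `attr(, "event_times")` / `attr(, "event_amps")`.
#'
#' @param config a [simConfig()].
#' @param duration recording length, s.
#' @return a voltage-clamp [Trace-class] (pA, inward negative).
#' @export
simulateSpontaneousPscs <- function(config, duration) {
  validateSimConfig(config)
  stopifnot(duration > 0)
  withLocalSeed(substreamSeed(config, "spsc"), {
    cfg <- config
    fs <- cfg$sampling_rate
    ns <- round(duration * fs)
    ev <- drawSpscEvents(cfg, duration)
    x <- renderEvents(ev$times, ev$amps, ns, fs, cfg$psp_rise_ms,
                      cfg$psp_decay_ms, sgn = -1) +
      stats::rnorm(ns, 0, cfg$noise_sd_pa)
    out <- Trace(x, samplingRate = fs, clampMode = "voltage_clamp")
    attr(out, "event_times") <- ev$times
    attr(out, "event_amps") <- ev$amps
    out
  })
}

#' Simulate an optogenetic circuit-mapping sweep
#'
#' One continuous voltage-clamp recording with periodic light pulses.
#' Each pulse triggers, for each of the `opto$n_connected` presynaptic
#' sources, one PSC at a latency drawn from
#' `Normal(latency_mean_ms, latency_jitter_ms)` with a per-pulse amplitude
#' drawn from the *same* log-normal law as the spontaneous PSCs (the
#' single-source equivalence the oPSC/sPSC ratio estimator rests on).
#' With probability `p_multiplet` a source fires a second spike 3-8 ms
#' later, producing a compound multiphasic oPSC.  Spontaneous PSCs run
#' throughout.  Optionally, brief large "runaway action currents" are
#' added at each pulse, emulating an opsin-expressing cell recorded in
#' voltage clamp, to exercise detector robustness.
#'
#' @param config a [simConfig()].
#' @param n_pulses number of light pulses.
#' @param ipi_s inter-pulse interval, s.
#' @param pre_s quiet segment before the first pulse, s.
#' @param spike_artifacts add action-current artifacts at each pulse?
#' @return a [ProtocolSweepSet-class] (protocol `"light_pulse"`, one trial,
#'   one cell `"post1"`) with `metadata$light_times` and ground truth in
#'   `metadata$ground_truth` (per-pulse evoked event times/amplitudes and
#'   the spontaneous event bookkeeping).
#' @export
simulateOptoTrial <- function(config, n_pulses = 30, ipi_s = 0.6,
                              pre_s = 0.5, spike_artifacts = FALSE) {
  validateSimConfig(config)
  withLocalSeed(substreamSeed(config, "opto"), {
    cfg <- config
    fs <- cfg$sampling_rate
    duration <- pre_s + n_pulses * ipi_s
    ns <- round(duration * fs)
    light_times <- pre_s + (seq_len(n_pulses) - 1) * ipi_s

    sp <- drawSpscEvents(cfg, duration)
    ev_t <- sp$times; ev_a <- sp$amps
    op_t <- numeric(0); op_a <- numeric(0)
    nc <- cfg$opto$n_connected
    if (nc > 0) for (lt in light_times) for (src in seq_len(nc)) {
      lat <- stats::rnorm(1, cfg$opto$latency_mean_ms,
                          cfg$opto$latency_jitter_ms) / 1000
      lat <- max(lat, 0.001)
      amp <- stats::rlnorm(1, log(cfg$spsc_amp_med), cfg$spsc_amp_sigma)
      op_t <- c(op_t, lt + lat); op_a <- c(op_a, amp)
      if (stats::runif(1) < cfg$opto$p_multiplet) {
        gap <- stats::runif(1, 0.003, 0.008)
        amp2 <- stats::rlnorm(1, log(cfg$spsc_amp_med), cfg$spsc_amp_sigma)
        op_t <- c(op_t, lt + lat + gap); op_a <- c(op_a, amp2)
      }
    }
    x <- renderEvents(c(ev_t, op_t), c(ev_a, op_a), ns, fs,
                      cfg$psp_rise_ms, cfg$psp_decay_ms, sgn = -1) +
      stats::rnorm(ns, 0, cfg$noise_sd_pa)
    if (spike_artifacts) {
      ## 0.6 ms triangular "runaway action current", ~600 pA
      wlen <- max(3L, round(6e-4 * fs))
      art <- -600 * (1 - abs(seq(-1, 1, length.out = wlen)))
      for (lt in light_times) {
        i0 <- round((lt + 0.002) * fs) + 1L
        idx <- i0:min(ns, i0 + wlen - 1L)
        x[idx] <- x[idx] + art[seq_along(idx)]
      }
    }
    stimv <- numeric(ns)
    for (lt in light_times)
      stimv[round(lt * fs) + seq_len(round(0.002 * fs))] <- 1
    trace <- Trace(x, samplingRate = fs, clampMode = "voltage_clamp",
                   stimulus = stimv)
    new("ProtocolSweepSet", protocol = "light_pulse",
        trials = list(list(post1 = trace)),
        metadata = list(light_times = light_times,
                        ground_truth = list(
                          n_connected = nc, opto_times = op_t,
                          opto_amps = op_a, spsc_times = ev_t,
                          spsc_amps = ev_a)))
  })
}

#' Simulate a light-ramp session
#'
#' A voltage-clamp recording of a baseline segment followed by a 5 s
#' linear light-intensity ramp.  In the oscillatory (cortex-like) regime
#' the ramp recruits a narrowband synaptic-current oscillation at
#' `ramp$osc_freq` (inside `ramp$osc_band`) whose envelope scales linearly
#' with light intensity; in the non-oscillatory (hypothalamus-like) regime
#' the ramp adds only a slow tonic inward current while spontaneous PSC
#' statistics are unchanged.
#'
#' Repeated ramp presentations are simulated as independent sweeps (fresh
#' spontaneous events, noise and oscillation phase per trial); per-cell
#' band-power summaries average spectrogram *power* across sweeps, which
#' is phase-insensitive.
#'
#' @param config a [simConfig()]; `config$ramp` controls the regime.
#' @param n_trials ramp presentations per cell.
#' @return a [Session-class] with one cell and one `light_ramp` sweep set
#'   of `n_trials` sweeps; metadata stores `ramp_onset_s` and
#'   `ramp_duration_s`.
#' @export
simulateRampSession <- function(config, n_trials = 5) {
  validateSimConfig(config)
  withLocalSeed(substreamSeed(config, "ramp"), {
    cfg <- config
    fs <- cfg$sampling_rate
    r <- cfg$ramp
    tail_s <- 0.25
    duration <- r$baseline_s + r$duration_s + tail_s
    ns <- round(duration * fs)
    tgrid <- (seq_len(ns) - 1) / fs
    light <- pmin(pmax((tgrid - r$baseline_s) / r$duration_s, 0), 1)
    light[tgrid >= r$baseline_s + r$duration_s] <- 0

    sp_all <- list()
    trialTrace <- function() {
      sp <- drawSpscEvents(cfg, duration)
      sp_all[[length(sp_all) + 1L]] <<- sp
      x <- renderEvents(sp$times, sp$amps, ns, fs, cfg$psp_rise_ms,
                        cfg$psp_decay_ms, sgn = -1)
      x <- x - r$tonic_amp_pa * light          # slow tonic inward current
      if (isTRUE(r$oscillatory)) {
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + r$osc_amp_pa * light * sin(2 * pi * r$osc_freq * tgrid + phi)
      }
      x <- x + stats::rnorm(ns, 0, cfg$noise_sd_pa)
      Trace(x, samplingRate = fs, clampMode = "voltage_clamp",
            stimulus = light)
    }
    tr <- lapply(seq_len(n_trials), function(i) list(post1 = trialTrace()))
    cl <- cellTable("post1",
                    region = if (cfg$preset == "lh") "LH" else "mPFC",
                    x_um = 0, y_um = 0)
    ss <- new("ProtocolSweepSet", protocol = "light_ramp", trials = tr,
              metadata = list(ramp_onset_s = r$baseline_s,
                              ramp_duration_s = r$duration_s))
    Session(cl, list(ss),
            groundTruth = list(oscillatory = isTRUE(r$oscillatory),
                               osc_freq = r$osc_freq,
                               osc_amp_pa = r$osc_amp_pa,
                               trial_events = sp_all))
  })
}
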