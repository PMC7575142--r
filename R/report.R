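#' Two-group comparison with the study's statistical toolkit
#'
#' Paired or unpaired Student's t test, Wilcoxon rank-sum or signed-rank
#' test, two-sided, with groups summarized as mean +/- sd.  Rank tests
#' use the exact distribution when both groups have at most 25
#' observations (and no ties), the normal approximation otherwise.  No
#' multiple-testing correction is applied.
#'
#' @param a,b numeric vectors (finite values).
#' @param test `"unpaired_t"`, `"paired_t"`, `"ranksum"` or
#'   `"signedrank"`.
#' @param metric label for the compared quantity.
#' @return one-row data.frame of class `"GroupComparison"`: `metric`,
#'   `test`, `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `statistic`, `p`.
#' @examples
#' compareGroups(rnorm(20), rnorm(20) + 2, test = "ranksum")
#' @export
compareGroups <- function(a, b,
                          test = c("unpaired_t", "paired_t", "ranksum",
                                   "signedrank"),
                          metric = "value") {
  test <- match.arg(test)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("groups must contain only finite values")
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  paired <- test %in% c("paired_t", "signedrank")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group lengths")
  exact <- max(length(a), length(b)) <= 25
  if (paired && all(a == b)) {
    ## degenerate case: no differences at all -> no evidence of a shift
    res <- list(statistic = 0, p.value = 1)
  } else res <- switch(test,
    unpaired_t = stats::t.test(a, b, paired = FALSE),
    paired_t = stats::t.test(a, b, paired = TRUE),
    ranksum = suppressWarnings(stats::wilcox.test(a, b, exact = exact)),
    signedrank = suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                     exact = exact)))
  out <- data.frame(metric = metric, test = test,
                    n_a = length(a), n_b = length(b),
                    mean_a = mean(a), sd_a = stats::sd(a),
                    mean_b = mean(b), sd_b = stats::sd(b),
                    statistic = unname(res$statistic), p = res$p.value,
                    stringsAsFactors = FALSE)
  class(out) <- c("GroupComparison", class(out))
  out
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Orchestrates simulate -> screen -> couple -> events -> spectral ->
#' compare on synthetic sessions and writes a CSV/JSON result bundle.
#' All randomness derives from `config$seed`: rerunning with the same
#' configuration reproduces every CSV byte for byte.
#'
#' @param config a [simConfig()].
#' @param out_dir output directory (created if needed).
#' @param stages which stages to run, in order.
#' @param n_trials trials per driven cell in the screening/coupling
#'   sessions.
#' @param n_pulses light pulses in the optogenetic sweep.
#' @return invisibly, a named list of the stage outputs; files written:
#'   `tests.csv`, `rates.csv`, `coupling.csv`, `events.csv`,
#'   `psc_stats.csv`, `spectral.csv`, `comparisons.csv`, `run_log.json`.
#' @export
runPipeline <- function(config, out_dir,
                        stages = c("screen", "couple", "events",
                                   "spectral", "compare"),
                        n_trials = 10, n_pulses = 30) {
  validateSimConfig(config)
  allowed <- c("screen", "couple", "events", "spectral", "compare")
  bad <- setdiff(stages, allowed)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("compare" %in% stages && !all(c("events", "spectral") %in% stages))
    stop("stage 'compare' requires stages 'events' and 'spectral'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wcsv <- function(df, file) utils::write.csv(
    df, file.path(out_dir, file), row.names = FALSE)

  if ("screen" %in% stages) {
    out$screen <- runStage("screen", {
      ses <- simulateConnectionSession(config, n_trials = n_trials)
      tests <- screenSession(ses)
      list(tests = tests, rates = rateTable(tests))
    })
    wcsv(out$screen$tests, "tests.csv")
    wcsv(out$screen$rates, "rates.csv")
  }
  if ("couple" %in% stages) {
    out$couple <- runStage("couple", {
      ses <- simulateCouplingSession(config, n_trials = n_trials)
      couplingTests(ses)
    })
    wcsv(out$couple, "coupling.csv")
  }
  if ("events" %in% stages) {
    out$events <- runStage("events", {
      sw <- simulateOptoTrial(config, n_pulses = n_pulses)
      tr <- sw@trials[[1]][[1]]
      ev <- detectEvents(tr, polarity = "inward",
                         rise_ms = config$psp_rise_ms,
                         decay_ms = config$psp_decay_ms)
      ev <- classifyOpto(ev, sw@metadata$light_times)
      list(events = ev, stats = eventStats(ev))
    })
    wcsv(out$events$events[, setdiff(names(out$events$events),
                                     character(0))], "events.csv")
    wcsv(out$events$stats, "psc_stats.csv")
  }
  if ("spectral" %in% stages) {
    out$spectral <- runStage("spectral", {
      cfg_on <- config; cfg_on$ramp$oscillatory <- TRUE
      cfg_off <- config; cfg_off$ramp$oscillatory <- FALSE
      inc_on <- rampPowerIncrease(simulateRampSession(cfg_on))
      inc_off <- rampPowerIncrease(simulateRampSession(cfg_off))
      rbind(cbind(condition = "oscillatory", inc_on),
            cbind(condition = "non_oscillatory", inc_off))
    })
    wcsv(out$spectral, "spectral.csv")
  }
  if ("compare" %in% stages) {
    out$compare <- runStage("compare", {
      ev <- out$events$events
      cmp <- list()
      sp <- ev$peak_amp_pA[ev$kind == "spontaneous"]
      op <- ev$peak_amp_pA[ev$kind == "optogenetic"]
      if (length(sp) >= 2 && length(op) >= 2)
        cmp$amp <- compareGroups(op, sp, test = "ranksum",
                                 metric = "oPSC_vs_sPSC_amplitude_pA")
      do.call(rbind, cmp)
    })
    if (!is.null(out$compare)) wcsv(out$compare, "comparisons.csv")
  }

  log <- list(package = "sparseconn",
              version = as.character(utils::packageVersion("sparseconn")),
              r_version = R.version.string,
              seed = config$seed, preset = config$preset,
              stages = stages, n_trials = n_trials, n_pulses = n_pulses,
              parameters = config[c("n_cells", "p_chem", "p_elec",
                                    "psp_amp", "spsc_rate", "spsc_amp_med",
                                    "spsc_amp_sigma")])
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
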