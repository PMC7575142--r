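#' Connection-rate table with exact binomial confidence intervals
#'
#' Tabulates detected connections by grouping keys and attaches the
#' connection rate with its exact (Clopper-Pearson) confidence interval
#' per group -- the appropriate interval in a regime where counts near
#' zero dominate.  Directed chemical tests and undirected coupling pairs
#' are tabulated as given (each simultaneously probed pair contributes two
#' directed chemical tests but one coupling pair).
#'
#' @param tests data.frame from [screenSession()] (column `detected`) or
#'   [couplingTests()] (column `coupled`).
#' @param by character vector of grouping columns (default: overall).
#' @param conf_level confidence level for the Clopper-Pearson interval.
#' @return data.frame with the grouping keys and `n_connected`,
#'   `n_tested`, `rate`, `ci_lower`, `ci_upper`.
#' @export
rateTable <- function(tests, by = character(), conf_level = 0.95) {
  hit_col <- if ("detected" %in% names(tests)) "detected" else "coupled"
  if (!hit_col %in% names(tests))
    stop("tests must have a 'detected' or 'coupled' column")
  key <- if (length(by)) interaction(tests[by], drop = TRUE, sep = " / ")
         else factor(rep("all", nrow(tests)))
  groups <- split(tests, key)
  rows <- lapply(names(groups), function(g) {
    n <- nrow(groups[[g]])
    if (n == 0L) { warning("empty group omitted: ", g); return(NULL) }
    k <- sum(groups[[g]][[hit_col]], na.rm = TRUE)
    ci <- rateFromCounts(k, n, conf_level)
    keyvals <- if (length(by)) groups[[g]][1, by, drop = FALSE]
               else data.frame(group = g, stringsAsFactors = FALSE)
    cbind(keyvals, ci, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Connection rate and Clopper-Pearson interval from counts
#'
#' @param n_connected detected connections.
#' @param n_tested tested connections (`>= n_connected`).
#' @param conf_level confidence level.
#' @return one-row data.frame: `n_connected`, `n_tested`, `rate`,
#'   `ci_lower`, `ci_upper`.
#' @examples
#' rateFromCounts(1, 2074)   # the screened chemical-connection rate
#' rateFromCounts(0, 50)     # rate 0, upper bound ~0.071
#' @export
rateFromCounts <- function(n_connected, n_tested, conf_level = 0.95) {
  stopifnot(n_tested >= 1, n_connected >= 0, n_connected <= n_tested)
  ci <- stats::binom.test(n_connected, n_tested,
                          conf.level = conf_level)$conf.int
  data.frame(n_connected = n_connected, n_tested = n_tested,
             rate = n_connected / n_tested,
             ci_lower = ci[1], ci_upper = ci[2])
}

#' Intersomatic-distance histogram split by group
#'
#' Bins the intersomatic distances of tested connections into half-open
#' bins `[lo, hi)` and reports a Wilcoxon rank-sum comparison of the
#' distance distributions between the two levels of `group`.
#'
#' @param tests data.frame with a `distance_um` column.
#' @param bin_um bin width, um.
#' @param group name of a two-level column to split by (default
#'   `"detected"` when present, else no split).
#' @return data.frame of bin counts (`bin_lo`, `bin_hi`, one count column
#'   per group level); when two groups are present, the rank-sum result is
#'   attached as `attr(, "ranksum")` (list with `statistic`, `p`).
#' @export
distanceHistogram <- function(tests, bin_um = 25, group = NULL) {
  d <- tests$distance_um
  if (is.null(d)) stop("tests must have a 'distance_um' column")
  keep <- is.finite(d)
  d <- d[keep]
  if (!length(d)) stop("no finite distances available")
  if (is.null(group) && "detected" %in% names(tests)) group <- "detected"
  g <- if (!is.null(group)) factor(tests[[group]][keep]) else
    factor(rep("all", length(d)))
  bins <- floor(d / bin_um)            # half-open [lo, hi): boundary -> upper
  lo <- seq(0, max(bins)) * bin_um
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_um)
  for (lev in levels(g)) {
    cnt <- tabulate(bins[g == lev] + 1L, nbins = length(lo))
    out[[paste0("n_", lev)]] <- cnt
  }
  if (nlevels(g) == 2L) {
    a <- d[g == levels(g)[1]]; b <- d[g == levels(g)[2]]
    if (length(a) && length(b)) {
      w <- suppressWarnings(stats::wilcox.test(a, b))
      attr(out, "ranksum") <- list(statistic = unname(w$statistic),
                                   p = w$p.value)
    }
  }
  out
}
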