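## Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores whatever RNG
#' state existed before the call, so internal randomness (e.g. Monte-Carlo
#' threshold calibration) never perturbs the caller's stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## scalar checks with field-naming errors (used by readers and constructors)
stopifNotScalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("field '", field, "' must be a finite numeric scalar", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## seconds -> milliseconds for reporting; time is stored in s throughout
sToMs <- function(x) 1000 * x
msToS <- function(x) x / 1000
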