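# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so that seeded generators do not disturb the caller's
#' random stream.  With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent configuration-error message naming the field
check_that <- function(ok, field, what) {
  if (!isTRUE(ok))
    stop(sprintf("invalid configuration: field '%s' %s", field, what),
         call. = FALSE)
  invisible(TRUE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x), field,
             "must be a finite number")
  if (strict_lower)
    check_that(x > lower, field, sprintf("must be > %g", lower))
  else
    check_that(x >= lower, field, sprintf("must be >= %g", lower))
  check_that(x <= upper, field, sprintf("must be <= %g", upper))
  invisible(TRUE)
}

# Draw `n` counts from a (mean, dispersion) spec.  dispersion is the
# variance-to-mean ratio: 0 -> deterministic, 1 -> Poisson, >1 -> negative
# binomial.  Counts are truncated below at `at_least`.
draw_counts <- function(n, spec, at_least = 0L) {
  mean <- spec$mean
  disp <- if (is.null(spec$dispersion)) 1 else spec$dispersion
  stopifnot(is.numeric(mean), mean >= 0, disp >= 0)
  k <- if (disp == 0) {
    rep(round(mean), n)
  } else if (disp <= 1) {
    rpois(n, mean)
  } else {
    # var = mean * disp  =>  size = mean / (disp - 1)
    rnbinom(n, size = mean / (disp - 1), mu = mean)
  }
  pmax(k, at_least)
}

# Draw positive values from a (mean, sd) spec via a gamma distribution
# (sd = 0 -> deterministic).
draw_positive <- function(n, spec) {
  mean <- spec$mean
  sdv <- if (is.null(spec$sd)) 0 else spec$sd
  stopifnot(mean >= 0, sdv >= 0)
  if (sdv == 0 || mean == 0) return(rep(mean, n))
  shape <- (mean / sdv)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}
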