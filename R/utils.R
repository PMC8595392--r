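## Internal helpers shared across modules.

#' Run code with a locally seeded RNG
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so seeded operations do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a root seed
#'
#' Deterministic, collision-unlikely mapping kept strictly below 2^31 so the
#' result is always a valid R integer seed. Pipelines use this to give each
#' stochastic stage its own stream from one root seed.
#'
#' @param seed root seed (integer-like)
#' @param k child index (integer-like, >= 0)
#' @return an integer seed
#' @export
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 104729 * (as.double(k) + 1)
  as.integer(s %% 2147483647L) + 1L
}

## argument checks -----------------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]"), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name, lower = min)
  if (x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

## small matrix helpers ------------------------------------------------------

#' Population-variance (denominator n) of each column
#' @noRd
col_pvar <- function(m) {
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}

is_pd2 <- function(m, tol = 0) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}
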