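# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed},
#' restoring the caller's RNG state afterwards so package functions never
#' clobber global random state.  With \code{seed = NULL} the expression uses
#' the current stream unchanged.
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer, got %s", deparse(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("%s must be TRUE or FALSE", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stopf("%s must be an integer >= %d", name, min)
  as.integer(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stopf("%s must lie in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  as.numeric(x)
}
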