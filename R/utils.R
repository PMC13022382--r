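# Internal helpers: deterministic seeding, argument checks, small numerics.

#' Derive a child seed from a root seed
#'
#' All stochastic generators in the package draw their randomness from a single
#' root seed that fans out deterministically to per-series child seeds, so that
#' a whole simulated experiment is reproducible from one integer while distinct
#' series get independent streams. The scheme is a Lehmer step modulo the
#' Mersenne prime 2^31 - 1:
#' `child = (root * 48271 + index * 2654435769) mod (2^31 - 1)`,
#' computed in double precision (exact below 2^53).
#'
#' @param root integer root seed.
#' @param index non-negative integer index of the child stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  stopifnot(is.numeric(index), all(index >= 0))
  m <- 2147483647
  s <- ((root %% m) * 48271 + (index %% m) * 2654435769) %% m
  as.integer(ifelse(s == 0, 1, s))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_badarg <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_badarg(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop_badarg(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_badarg(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Quadratic (parabolic) refinement of a grid argmax: vertex of the parabola
# through (x[i-1], y[i-1]), (x[i], y[i]), (x[i+1], y[i+1]). Assumes a uniform
# or near-uniform local spacing; falls back to x[i] for a degenerate parabola.
quad_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  d1 <- (y[i + 1] - y[i - 1]) / 2
  d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  h <- (x[i + 1] - x[i - 1]) / 2
  if (!is.finite(d2) || d2 >= 0 || abs(d2) < .Machine$double.eps) return(x[i])
  delta <- -d1 / d2
  delta <- max(min(delta, 1), -1)
  x[i] + delta * h
}
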