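# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw from a multivariate normal distribution
#'
#' Cholesky-based sampler used throughout the synthetic-data and resampling
#' code. Kept internal-but-exported so tests and scripts can build small
#' Gaussian fixtures without extra dependencies.
#'
#' @param n Number of draws.
#' @param mu Mean vector.
#' @param sigma Positive semi-definite covariance matrix.
#' @return An `n x length(mu)` matrix.
#' @export
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2L, mu, `+`)
}

# Symmetry check with tolerance; returns TRUE/FALSE.
is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Fast stable log-determinant via Cholesky; stops on non-PD.
logdet_pd <- function(m) {
  2 * sum(log(diag(chol(m))))
}

# Deterministic child seeds: derive a stream of sub-seeds below 2^31 from a
# master seed, so that independent stages never share an RNG stream.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

# Run expr under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
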