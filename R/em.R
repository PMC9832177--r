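# EM estimation of an unstructured Gaussian mean/covariance under MAR
# missingness. Used directly for network input matrices and internally for
# the saturated-model log-likelihood that anchors chi-square fit statistics.

# Group rows of a data matrix by missingness pattern. Returns a list of
# components with idx (observed column indices), rows, n, and (if wanted)
# the per-pattern mean and ML covariance of the observed block.
missing_patterns <- function(x, stats = TRUE) {
  obs <- !is.na(x)
  keep <- rowSums(obs) > 0
  x <- x[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  out <- lapply(split(seq_len(nrow(x)), key), function(rows) {
    idx <- which(obs[rows[1], ])
    p <- list(idx = idx, rows = rows, n = length(rows))
    if (stats) {
      xo <- x[rows, idx, drop = FALSE]
      p$mean <- colMeans(xo)
      xc <- sweep(xo, 2L, p$mean)
      p$cov <- crossprod(xc) / p$n          # ML (n) denominator
    }
    p
  })
  attr(out, "n_used") <- nrow(x)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Observed-data -2 log-likelihood of (mu, sigma) under the pattern list.
fiml_m2ll <- function(patterns, mu, sigma) {
  tot <- 0
  for (p in patterns) {
    o <- p$idx
    so <- sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(so), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    ld <- 2 * sum(log(diag(ch)))
    si <- chol2inv(ch)
    d <- p$mean - mu[o]
    a <- p$cov + tcrossprod(d)
    tot <- tot + p$n * (length(o) * log(2 * pi) + ld + sum(si * a))
  }
  tot
}

#' EM estimate of a Gaussian mean and covariance with missing data
#'
#' Maximum-likelihood estimation of an unstructured multivariate-normal mean
#' vector and covariance matrix from incompletely observed rows (missing at
#' random). On complete data this reduces exactly to the sample moments (ML,
#' `n` denominator).
#'
#' @param x Numeric matrix (rows = cases) with `NA` for missing entries.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the relative change in observed-data
#'   log-likelihood (default 1e-10).
#' @return List with `mean`, `cov` (ML), `n_effective` (rows with at least
#'   one observation), `loglik`, `iterations`, `converged`.
#' @export
em_covariance <- function(x, max_iter = 500, tol = 1e-10) {
  x <- as.matrix(x)
  k <- ncol(x)
  obs_frac <- colMeans(!is.na(x))
  if (any(obs_frac < 0.10)) {
    stop("variable(s) observed for <10% of rows: ",
         paste(colnames(x)[obs_frac < 0.10], collapse = ", "))
  }
  pats <- missing_patterns(x)
  n <- attr(pats, "n_used")
  complete <- length(pats) == 1 && length(pats[[1]]$idx) == k
  if (complete) {
    p <- pats[[1]]
    ll <- -0.5 * fiml_m2ll(pats, p$mean, p$cov)
    return(list(mean = p$mean, cov = p$cov, n_effective = n,
                loglik = ll, iterations = 0L, converged = TRUE))
  }
  # Start from available-case moments, ridge-repaired to PD.
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- stats::cov(x, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * max(ev)) {
    sigma <- sigma + diag(max(ev) * 1e-4 + 1e-8, k)
  }
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    t1 <- numeric(k)
    t2 <- matrix(0, k, k)
    for (p in pats) {
      o <- p$idx; ms <- setdiff(seq_len(k), o)
      xo_mean <- p$mean
      if (!length(ms)) {
        t1[o] <- t1[o] + p$n * xo_mean
        t2[o, o] <- t2[o, o] + p$n * (p$cov + tcrossprod(xo_mean))
        next
      }
      soo_inv <- solve(sigma[o, o, drop = FALSE])
      B <- sigma[ms, o, drop = FALSE] %*% soo_inv        # regression coefs
      d <- xo_mean - mu[o]
      m_mean <- mu[ms] + as.vector(B %*% d)
      C <- sigma[ms, ms, drop = FALSE] - B %*% sigma[o, ms, drop = FALSE]
      # Sufficient statistics aggregated at the pattern level.
      t1[o] <- t1[o] + p$n * xo_mean
      t1[ms] <- t1[ms] + p$n * m_mean
      t2[o, o] <- t2[o, o] + p$n * (p$cov + tcrossprod(xo_mean))
      # Sum over rows of E[x_m x_o'] = n (m_mean xbar_o' + B S_o)
      cross <- p$n * (tcrossprod(m_mean, xo_mean) + B %*% p$cov)
      t2[ms, o] <- t2[ms, o] + cross
      t2[o, ms] <- t2[o, ms] + t(cross)
      t2[ms, ms] <- t2[ms, ms] + p$n *
        (C + tcrossprod(m_mean) + B %*% p$cov %*% t(B))
      # (uses E[x_m x_m'] = Var + E E', Var = C + B S_oo,within B')
    }
    mu <- t1 / n
    sigma <- t2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- -0.5 * fiml_m2ll(pats, mu, sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop(sprintf("EM did not converge in %d iterations (last loglik %.6f)",
                 max_iter, ll_old))
  }
  nm <- colnames(x)
  names(mu) <- nm; dimnames(sigma) <- list(nm, nm)
  list(mean = mu, cov = sigma, n_effective = n, loglik = ll_old,
       iterations = it, converged = TRUE)
}
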