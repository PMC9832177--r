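# Shared fixtures and independent oracles used across the test suite.
# Everything here is generated in code; no stored data.

# One-factor indicator data with known loadings (unit-variance indicators).
gen_one_factor <- function(n, lam, seed = 1) {
  stopifnot(all(lam^2 < 1))
  withr_seed(seed, {
    f <- stats::rnorm(n)
    x <- vapply(seq_along(lam), function(j) {
      lam[j] * f + stats::rnorm(n, sd = sqrt(1 - lam[j]^2))
    }, numeric(n))
    colnames(x) <- paste0("v", seq_along(lam))
    x
  })
}

# Minimal local with_seed that restores RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# RI-CLPM generator with explicit truth (two series).
gen_riclpm_panel <- function(n, waves, a_ii = 0.45, a_ee = 0.45,
                             c_ie = 0, c_ei = 0, ri_var = c(4, 9),
                             ri_cor = 0.5, wvar = c(2, 2), wcov = 0.5,
                             seed = 1) {
  withr_seed(seed, {
    W <- length(waves)
    ri_cov <- ri_cor * sqrt(prod(ri_var))
    ri <- rmvn(n, c(0, 0), matrix(c(ri_var[1], ri_cov, ri_cov, ri_var[2]), 2))
    Sw <- matrix(c(wvar[1], wcov, wcov, wvar[2]), 2)
    # Row 1 = int equation, row 2 = ext equation (column-major fill):
    # A[1,1]=a_ii, A[2,1]=c_ie (int -> ext), A[1,2]=c_ei (ext -> int), A[2,2]=a_ee
    A <- matrix(c(a_ii, c_ie, c_ei, a_ee), 2)
    x <- array(NA_real_, c(n, W, 2))
    d <- rmvn(n, c(0, 0), Sw)
    x[, 1, ] <- ri + d
    for (w in 2:W) {
      d <- d %*% t(A) + rmvn(n, c(0, 0), Sw)
      x[, w, ] <- ri + d
    }
    panel_data(x, paste0("s", seq_len(n)), waves, c("int", "ext"))
  })
}

# Random positive-definite correlation-ish matrix.
random_pd <- function(p, seed) {
  withr_seed(seed, {
    A <- matrix(stats::rnorm(p * p), p)
    stats::cov2cor(crossprod(A) + diag(p) * 0.5)
  })
}

# ---- Independent oracle: bifactor index arithmetic (straight transcription
# of the ECV / omega-family / H formulas, written without reference to the
# package implementation).
oracle_bifactor_indices <- function(lg, ls, domains, theta) {
  doms <- sort(unique(domains))
  common <- sum(lg^2) + sum(ls^2)
  vt <- sum(lg)^2 + sum(sapply(doms, function(d) sum(ls[domains == d])^2)) +
    sum(theta)
  H <- function(l) {
    s <- sum(l^2 / (1 - l^2)); s / (1 + s)
  }
  out <- list()
  om <- (sum(lg)^2 + sum(sapply(doms, function(d) sum(ls[domains == d])^2))) / vt
  omh <- sum(lg)^2 / vt
  out$general <- c(ecv = sum(lg^2) / common, ecv_ss = sum(lg^2) / common,
                   omega = om, omega_h = omh, relative_omega = omh / om,
                   H = H(lg))
  for (d in doms) {
    i <- domains == d
    den <- sum(lg[i])^2 + sum(ls[i])^2 + sum(theta[i])
    os <- (sum(lg[i])^2 + sum(ls[i])^2) / den
    ohs <- sum(ls[i])^2 / den
    out[[d]] <- c(ecv = sum(ls[i]^2) / common,
                  ecv_ss = sum(ls[i]^2) / (sum(lg[i]^2) + sum(ls[i]^2)),
                  omega = os, omega_h = ohs, relative_omega = ohs / os,
                  H = H(ls[i]))
  }
  out
}

# ---- Independent oracle: exhaustive EBIC minimization over all edge sets
# of a small GGM (uses only the package's constrained-MLE primitive, which
# is itself validated against closed forms elsewhere).
oracle_exhaustive_ggm <- function(S, n, gamma = 0.5) {
  p <- ncol(S)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- NULL
  for (code in 0:(2^m - 1)) {
    adj <- matrix(FALSE, p, p)
    bits <- as.integer(intToBits(code))[seq_len(m)] == 1L
    for (r in which(bits)) {
      adj[pairs[r, 1], pairs[r, 2]] <- adj[pairs[r, 2], pairs[r, 1]] <- TRUE
    }
    fit <- pmutual:::ggm_constrained_mle(S, adj)
    sc <- pmutual:::ggm_ebic(fit$K, S, n, gamma)
    if (is.null(best) || sc$ebic < best$ebic) best <- list(adj = adj, ebic = sc$ebic)
  }
  best
}

# ---- Independent oracle: all-pairs shortest paths (Floyd-Warshall) and
# centrality from first principles on a small weighted graph.
oracle_centrality <- function(w) {
  p <- nrow(w)
  len <- ifelse(w != 0, 1 / abs(w), Inf)
  diag(len) <- 0
  D <- len
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  clo <- sapply(seq_len(p), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) 0 else (p - 1) / sum(d)
  })
  list(dist = D, closeness = clo, ei = rowSums(w))
}
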