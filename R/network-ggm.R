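# Gaussian graphical models: within/between decomposition of panels,
# constrained (unregularized) precision estimation for a fixed edge set,
# and EBIC-guided model selection (threshold-grid candidates followed by
# greedy single-edge search).

#' Split a panel into between- and within-person datasets
#'
#' Computes each subject's grand mean per variable over their observed waves
#' (the between-person dataset, one row per subject) and the wave-wise
#' deviations from that mean (the within-person dataset). The decomposition
#' is exact: mean + deviation reconstructs every observed value. Subjects
#' with fewer than two observed waves on a variable contribute no deviation
#' for it; subjects with fewer than two observed waves overall are excluded
#' from the within data (counted in `dropped_subjects`).
#'
#' @param panel A [panel_data].
#' @return List with `between` (subject x variable matrix of person means),
#'   `within` (a [panel_data] of deviations), `dropped_subjects` (count).
#' @export
center_within <- function(panel) {
  n <- dim(panel)[1]; W <- dim(panel)[2]; k <- dim(panel)[3]
  waves_per_subject <- apply(panel$mask, 1,
                             function(m) sum(rowSums(matrix(m, W, k)) > 0))
  keep <- waves_per_subject >= 2
  between <- matrix(NA_real_, n, k,
                    dimnames = list(panel$subject_ids, panel$variables))
  dev <- panel$values
  for (j in seq_len(k)) {
    vj <- panel$values[, , j]
    mj <- rowMeans(vj, na.rm = TRUE)
    mj[!is.finite(mj)] <- NA_real_
    between[, j] <- mj
    dev[, , j] <- vj - mj
  }
  dev[!keep, , ] <- NA_real_
  within <- panel_data(dev, panel$subject_ids, panel$waves, panel$variables)
  list(between = between, within = within,
       dropped_subjects = sum(!keep))
}

# Partial correlation matrix from a precision matrix.
precision_to_pcor <- function(K) {
  d <- sqrt(diag(K))
  pc <- -K / outer(d, d)
  diag(pc) <- 0
  (pc + t(pc)) / 2
}

# Constrained Gaussian ML: maximize logdet(K) - tr(SK) subject to K[i,j]=0
# off the edge set. Classical modified-regression algorithm (iterating
# neighborhood regressions on the working covariance).
ggm_constrained_mle <- function(S, adj, max_iter = 200, tol = 1e-10) {
  p <- ncol(S)
  diag(adj) <- FALSE
  W <- S
  if (p == 1 || !any(adj)) {
    K <- diag(1 / diag(S), p)
    W <- diag(diag(S), p)
    return(list(K = K, W = W, iterations = 0L))
  }
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      nb <- which(adj[, j])
      w12 <- numeric(p - 1)
      idx <- setdiff(seq_len(p), j)
      if (length(nb)) {
        W11 <- W[nb, nb, drop = FALSE]
        beta <- solve(W11, S[nb, j])
        w12_full <- W[idx, nb, drop = FALSE] %*% beta
        w12 <- as.vector(w12_full)
      }
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol * max(1, max(abs(S)))) break
  }
  # Recover K from the final W by blockwise inversion per column.
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    nb <- which(adj[, j])
    idx <- setdiff(seq_len(p), j)
    beta_full <- numeric(p - 1)
    if (length(nb)) {
      beta <- solve(W[nb, nb, drop = FALSE], S[nb, j])
      beta_full[match(nb, idx)] <- beta
    }
    k22 <- 1 / (S[j, j] - if (length(nb)) sum(W[idx, j] * beta_full) else 0)
    K[j, j] <- k22
    K[idx, j] <- -beta_full * k22
  }
  K <- (K + t(K)) / 2
  K[!adj & !diag(p)] <- 0
  list(K = K, W = W, iterations = it)
}

# Gaussian log-likelihood (covariance part, ML profile over the mean) and
# EBIC of a precision matrix K for sample covariance S at size n.
ggm_ebic <- function(K, S, n, gamma) {
  p <- ncol(K)
  E <- sum(K[upper.tri(K)] != 0)
  ll <- (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] -
                     sum(S * K) - p * log(2 * pi))
  list(loglik = ll,
       ebic = -2 * ll + E * log(n) + 4 * E * gamma * log(p),
       n_edges = E)
}

#' Estimate an unregularized Gaussian graphical model by EBIC search
#'
#' Two-stage edge-set selection: candidate sparsity patterns are generated
#' by thresholding the saturated partial-correlation matrix over a grid of
#' levels, each candidate is refitted by constrained (unpenalized) maximum
#' likelihood and scored with the extended BIC; a greedy single-edge
#' add/remove search then refines the best candidate until the EBIC no
#' longer improves. Returned edge weights are the partial correlations of
#' the final unpenalized fit.
#'
#' @param cov Positive-definite covariance matrix (or a data matrix when
#'   `n` is omitted, in which case moments are taken from the data; rows
#'   with missing values are handled by [em_covariance]).
#' @param n Sample size behind `cov`.
#' @param ebic_gamma EBIC sparsity weight (default 0.5).
#' @param n_thresholds Size of the stage-1 candidate grid (default 100).
#' @param level,wave Optional metadata labels stored on the network.
#' @return Object of class `ggm_network`: `weights` (symmetric partial
#'   correlations, zero diagonal), `precision`, `adjacency`, `ebic`,
#'   `n`, `ebic_gamma`, `level`, `wave`, `node_names`.
#' @export
estimate_ggm <- function(cov, n = NULL, ebic_gamma = 0.5, n_thresholds = 100,
                         level = NA_character_, wave = NA_integer_) {
  if (is.null(n)) {
    x <- as.matrix(cov)
    em <- em_covariance(x)
    cov <- em$cov
    n <- em$n_effective
  }
  S <- as.matrix(cov)
  p <- ncol(S)
  if (n <= p) stop("n must exceed the number of nodes")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive definite")
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(nodes, nodes)

  score_pattern <- function(adj) {
    fit <- ggm_constrained_mle(S, adj)
    sc <- ggm_ebic(fit$K, S, n, ebic_gamma)
    list(adj = adj, K = fit$K, ebic = sc$ebic, loglik = sc$loglik,
         n_edges = sc$n_edges)
  }
  # Stage 1: threshold grid on saturated partial correlations.
  pc_sat <- precision_to_pcor(solve(S))
  apc <- abs(pc_sat[upper.tri(pc_sat)])
  thr <- unique(c(0, stats::quantile(
    apc, probs = seq(0, 1, length.out = n_thresholds), names = FALSE), Inf))
  best <- NULL
  seen <- character(0)
  for (t in thr) {
    adj <- abs(pc_sat) > t
    diag(adj) <- FALSE
    key <- paste(which(adj[upper.tri(adj)]), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    cand <- score_pattern(adj)
    if (is.null(best) || cand$ebic < best$ebic - 1e-12) best <- cand
  }
  # Stage 2: greedy single-edge add/remove until no move improves EBIC.
  pairs <- which(upper.tri(matrix(TRUE, p, p)), arr.ind = TRUE)
  repeat {
    improved <- FALSE
    best_move <- best
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      adj <- best$adj
      adj[i, j] <- adj[j, i] <- !adj[i, j]
      cand <- score_pattern(adj)
      if (cand$ebic < best_move$ebic - 1e-10) {
        best_move <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
    best <- best_move
  }
  weights <- precision_to_pcor(best$K)
  dimnames(weights) <- list(nodes, nodes)
  structure(list(node_names = nodes, weights = weights,
                 precision = best$K, adjacency = best$adj,
                 n = n, ebic_gamma = ebic_gamma, ebic = best$ebic,
                 loglik = best$loglik, n_edges = best$n_edges,
                 level = level, wave = wave),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("<ggm_network> %d nodes, %d edges (EBIC gamma %.2f, n = %d%s%s)\n",
              length(x$node_names), x$n_edges, x$ebic_gamma, x$n,
              if (!is.na(x$level)) paste0(", ", x$level) else "",
              if (!is.na(x$wave)) paste0(", age ", x$wave) else ""))
  invisible(x)
}

#' @export
plot.ggm_network <- function(x, ...) {
  g <- ggm_igraph(x)
  ew <- igraph::E(g)$weight
  igraph::plot.igraph(
    g, edge.width = 4 * abs(ew),
    edge.color = ifelse(ew > 0, "darkgreen", "firebrick"),
    layout = igraph::layout_with_fr(g), ...)
  invisible(x)
}

# igraph view of a network, abs weights as edge attribute "length-weight".
ggm_igraph <- function(network, binary = FALSE) {
  w <- network$weights
  adj <- w != 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (!binary) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- w[el]
  }
  igraph::V(g)$name <- network$node_names
  g
}

#' Write a network as GraphML and/or a square CSV weight matrix
#'
#' @param network A `ggm_network`.
#' @param graphml_path,csv_path Optional output paths.
#' @return The network, invisibly.
#' @export
write_network <- function(network, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(network$weights, csv_path, row.names = TRUE)
  }
  if (!is.null(graphml_path)) {
    g <- ggm_igraph(network)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}

# Fast saturated (no model selection) partial-correlation network; used as
# the default estimator inside permutation/bootstrap loops.
saturated_ggm <- function(S, n, level = NA_character_, wave = NA_integer_) {
  nodes <- colnames(S) %||% paste0("V", seq_len(ncol(S)))
  K <- solve(S)
  w <- precision_to_pcor(K)
  dimnames(w) <- list(nodes, nodes)
  structure(list(node_names = nodes, weights = w, precision = K,
                 adjacency = w != 0, n = n, ebic_gamma = NA_real_,
                 ebic = NA_real_, loglik = NA_real_,
                 n_edges = sum(w[upper.tri(w)] != 0),
                 level = level, wave = wave),
            class = "ggm_network")
}

# Internal: estimate a network from a raw data matrix with the requested
# estimator.
fit_network <- function(x, estimator = c("ebic", "saturated"),
                        ebic_gamma = 0.5, level = NA_character_,
                        wave = NA_integer_) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  if (anyNA(x)) {
    em <- em_covariance(x)
    S <- em$cov; n <- em$n_effective
  } else {
    mu <- colMeans(x)
    S <- crossprod(sweep(x, 2L, mu)) / nrow(x)
    n <- nrow(x)
  }
  if (estimator == "ebic") {
    estimate_ggm(S, n, ebic_gamma = ebic_gamma, level = level, wave = wave)
  } else {
    saturated_ggm(S, n, level = level, wave = wave)
  }
}
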