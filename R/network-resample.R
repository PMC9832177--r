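# Resampling machinery for networks: non-parametric edge bootstraps with
# difference tests, case-drop centrality stability (CS-coefficients), and
# the permutation network comparison test (M and S statistics).

# Upper-triangle edge vector with stable names.
edge_vector <- function(w) {
  nodes <- colnames(w)
  ut <- upper.tri(w)
  idx <- which(ut, arr.ind = TRUE)
  stats::setNames(w[ut], paste0(nodes[idx[, 1]], "--", nodes[idx[, 2]]))
}

#' Non-parametric edge bootstrap with difference tests
#'
#' Resamples subjects with replacement, re-estimates the network per
#' resample, and reports 95% percentile confidence intervals per edge plus
#' bootstrap difference tests for all edge pairs and all node pairs per
#' centrality metric (a difference is flagged significant when its bootstrap
#' CI excludes 0).
#'
#' @param x Data matrix (rows = cases) from which the network is estimated.
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed (resampling is exactly reproducible).
#' @param estimator `"ebic"` or `"saturated"` (see [estimate_ggm]).
#' @param ebic_gamma EBIC gamma for the `"ebic"` estimator.
#' @param max_failure_frac Error out if more than this fraction of bootstrap
#'   fits fail (default 0.05).
#' @return List of class `edge_bootstrap`: `network` (point estimate),
#'   `edge_ci` (data frame), `edge_diff` / `centrality_diff` (data frames
#'   of pairwise tests), `B`, `failures`.
#' @export
bootstrap_edges <- function(x, B = 500, seed = 1,
                            estimator = c("ebic", "saturated"),
                            ebic_gamma = 0.5, max_failure_frac = 0.05) {
  estimator <- match.arg(estimator)
  if (B < 200) stop("B must be at least 200")
  x <- as.matrix(x)
  n <- nrow(x)
  net <- fit_network(x, estimator, ebic_gamma)
  est_edges <- edge_vector(net$weights)
  cent <- centrality(net)
  metrics <- c("closeness", "betweenness", "expected_influence")
  boot_edges <- matrix(NA_real_, B, length(est_edges),
                       dimnames = list(NULL, names(est_edges)))
  boot_cent <- lapply(metrics, function(m)
    matrix(NA_real_, B, nrow(cent), dimnames = list(NULL, cent$node)))
  names(boot_cent) <- metrics
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      rows <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(fit_network(x[rows, , drop = FALSE], estimator,
                                  ebic_gamma),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failures <- failures + 1L
        next
      }
      boot_edges[b, ] <- edge_vector(fit$weights)
      cb <- centrality(fit)
      for (m in metrics) boot_cent[[m]][b, ] <- cb[[m]]
    }
  })
  if (failures > max_failure_frac * B) {
    stop(failures, " of ", B, " bootstrap fits failed")
  }
  ok <- !is.na(boot_edges[, 1])
  qs <- apply(boot_edges[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  edge_ci <- data.frame(edge = names(est_edges), estimate = unname(est_edges),
                        lower = qs[1, ], upper = qs[2, ],
                        stringsAsFactors = FALSE)
  rownames(edge_ci) <- NULL
  pair_tests <- function(mat, values, labels) {
    m <- ncol(mat)
    if (m < 2) return(NULL)
    pr <- utils::combn(m, 2)
    data.frame(
      a = labels[pr[1, ]], b = labels[pr[2, ]],
      difference = values[pr[1, ]] - values[pr[2, ]],
      lower = vapply(seq_len(ncol(pr)), function(q) {
        stats::quantile(mat[ok, pr[1, q]] - mat[ok, pr[2, q]], 0.025)
      }, 0),
      upper = vapply(seq_len(ncol(pr)), function(q) {
        stats::quantile(mat[ok, pr[1, q]] - mat[ok, pr[2, q]], 0.975)
      }, 0),
      stringsAsFactors = FALSE
    ) |> (\(d) {d$significant <- d$lower > 0 | d$upper < 0; d})()
  }
  edge_diff <- pair_tests(boot_edges, est_edges, names(est_edges))
  centrality_diff <- lapply(metrics, function(m)
    pair_tests(boot_cent[[m]], cent[[m]], cent$node))
  names(centrality_diff) <- metrics
  structure(list(network = net, edge_ci = edge_ci, edge_diff = edge_diff,
                 centrality_diff = centrality_diff, B = B, seed = seed,
                 failures = failures, boot_edges = boot_edges),
            class = "edge_bootstrap")
}

#' Case-drop bootstrap and the correlation-stability coefficient
#'
#' For each drop proportion in `drop_grid`, repeatedly re-estimates the
#' network on random subsamples and correlates the subsample centrality with
#' the full-sample centrality across nodes. The CS-coefficient is the
#' largest drop proportion at which at least 95% of subsamples keep that
#' correlation at or above .70; labels follow the .70/.50/.25 tiers
#' (excellent/good/fair, else poor).
#'
#' @param x Data matrix.
#' @param metric Centrality metric (default `"expected_influence"`).
#' @param B Subsamples per grid point (>= 200 for production use; smaller
#'   values are allowed for quick checks and flagged in the result).
#' @param drop_grid Proportions in (0, 0.75].
#' @param seed Integer seed.
#' @param estimator,ebic_gamma As in [bootstrap_edges].
#' @return List of class `cs_result`: `cs`, `label`, `grid` (data frame of
#'   per-proportion retention rates), `metric`.
#' @export
case_drop_cs <- function(x, metric = "expected_influence", B = 200,
                         drop_grid = seq(0.1, 0.75, by = 0.05), seed = 1,
                         estimator = c("ebic", "saturated"),
                         ebic_gamma = 0.5) {
  estimator <- match.arg(estimator)
  stopifnot(all(drop_grid > 0 & drop_grid <= 0.75))
  x <- as.matrix(x)
  n <- nrow(x)
  net <- fit_network(x, estimator, ebic_gamma)
  cent0 <- centrality(net)[[metric]]
  grid <- data.frame(drop = sort(drop_grid), retain_rate = NA_real_)
  with_seed(seed, {
    for (gi in seq_len(nrow(grid))) {
      keep_n <- max(3, round(n * (1 - grid$drop[gi])))
      cors <- vapply(seq_len(B), function(b) {
        rows <- sample.int(n, keep_n)
        fit <- tryCatch(fit_network(x[rows, , drop = FALSE], estimator,
                                    ebic_gamma), error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        cb <- centrality(fit)[[metric]]
        if (stats::sd(cb) < 1e-12 || stats::sd(cent0) < 1e-12) {
          # A constant centrality profile carries no rank information;
          # counted as not retained (conservative).
          return(0)
        }
        stats::cor(cent0, cb)
      }, 0)
      grid$retain_rate[gi] <- mean(cors >= 0.70, na.rm = TRUE)
    }
  })
  passing <- grid$drop[grid$retain_rate >= 0.95]
  cs <- if (length(passing)) max(passing) else 0
  label <- if (cs > 0.70) "excellent" else if (cs > 0.50) "good" else
    if (cs > 0.25) "fair" else "poor"
  structure(list(cs = cs, label = label, grid = grid, metric = metric,
                 B = B, seed = seed, small_B = B < 200),
            class = "cs_result")
}

#' Permutation network comparison test
#'
#' Compares two networks estimated from independent groups (or paired
#' within-subject datasets): the M statistic is the maximum absolute edge
#' difference (structural invariance), the S statistic the absolute
#' difference in global strength (sum of absolute edge weights by default).
#' The null distribution permutes group labels (unpaired) or swaps dataset
#' membership within subject pairs (paired); p-values are the proportion of
#' permuted statistics at or above the observed one. When M is significant,
#' per-edge permutation tests with Holm adjustment localize the differences.
#' The paired mode is provided for within-subject age comparisons but should
#' be treated as experimental.
#'
#' @param xa,xb Data matrices with identical column sets (same node order);
#'   for `paired = TRUE` they must have equal row counts with aligned rows.
#' @param n_perm Number of permutations (>= 500 recommended).
#' @param paired Permute within row pairs instead of across groups.
#' @param seed Integer seed.
#' @param estimator,ebic_gamma Network estimator used for observed and
#'   permuted statistics alike (default `"saturated"` for tractability).
#' @param strength `"absolute"` (sum of |edges|, default) or `"signed"`.
#' @param alpha Significance level gating the per-edge follow-up (default
#'   .05).
#' @return List of class `nct_result`: `M`, `p_M`, `S`, `p_S`, `edge_tests`
#'   (with Holm-adjusted p; `NULL` unless M significant), `n_perm`, `seed`.
#' @export
nct <- function(xa, xb, n_perm = 1000, paired = FALSE, seed = 1,
                estimator = c("saturated", "ebic"), ebic_gamma = 0.5,
                strength = c("absolute", "signed"), alpha = 0.05) {
  estimator <- match.arg(estimator)
  strength <- match.arg(strength)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (!identical(colnames(xa), colnames(xb))) {
    stop("node sets (column names) must match")
  }
  if (paired && nrow(xa) != nrow(xb)) stop("paired mode needs aligned rows")
  strength_of <- function(w) {
    e <- w[upper.tri(w)]
    if (strength == "absolute") sum(abs(e)) else abs(sum(e))
  }
  stat_pair <- function(a, b) {
    na_ <- fit_network(a, estimator, ebic_gamma)
    nb_ <- fit_network(b, estimator, ebic_gamma)
    dw <- na_$weights - nb_$weights
    list(M = max(abs(dw[upper.tri(dw)])),
         S = abs(strength_of(na_$weights) - strength_of(nb_$weights)),
         edges = edge_vector(dw))
  }
  obs <- stat_pair(xa, xb)
  na <- nrow(xa); nb <- nrow(xb)
  pooled <- rbind(xa, xb)
  perm_M <- numeric(n_perm); perm_S <- numeric(n_perm)
  perm_edges <- matrix(NA_real_, n_perm, length(obs$edges))
  with_seed(seed, {
    for (q in seq_len(n_perm)) {
      if (paired) {
        swap <- stats::runif(na) < 0.5
        a <- xa; b <- xb
        a[swap, ] <- xb[swap, ]; b[swap, ] <- xa[swap, ]
      } else {
        idx <- sample.int(na + nb, na)
        a <- pooled[idx, , drop = FALSE]
        b <- pooled[-idx, , drop = FALSE]
      }
      st <- stat_pair(a, b)
      perm_M[q] <- st$M; perm_S[q] <- st$S
      perm_edges[q, ] <- st$edges
    }
  })
  p_M <- (1 + sum(perm_M >= obs$M - 1e-12)) / (n_perm + 1)
  p_S <- (1 + sum(perm_S >= obs$S - 1e-12)) / (n_perm + 1)
  edge_tests <- NULL
  if (p_M <= alpha) {
    praw <- vapply(seq_along(obs$edges), function(e) {
      (1 + sum(abs(perm_edges[, e]) >= abs(obs$edges[e]) - 1e-12)) /
        (n_perm + 1)
    }, 0)
    edge_tests <- data.frame(
      edge = names(obs$edges), difference = unname(obs$edges),
      p = praw, p_holm = stats::p.adjust(praw, "holm"),
      stringsAsFactors = FALSE)
    edge_tests$significant <- edge_tests$p_holm <= alpha
    rownames(edge_tests) <- NULL
  }
  structure(list(M = obs$M, p_M = p_M, S = obs$S, p_S = p_S,
                 edge_tests = edge_tests, n_perm = n_perm, seed = seed,
                 paired = paired, estimator = estimator,
                 strength = strength),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("<nct_result%s> M = %.4f (p = %.4g), S = %.4f (p = %.4g), %d permutations\n",
              if (x$paired) " paired" else "", x$M, x$p_M, x$S, x$p_S,
              x$n_perm))
  if (!is.null(x$edge_tests)) {
    sig <- x$edge_tests[x$edge_tests$significant, , drop = FALSE]
    cat("  Holm-significant edges:",
        if (nrow(sig)) paste(sig$edge, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
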