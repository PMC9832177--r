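# GGM estimation, centering decomposition, EM covariance, centrality,
# small-worldness, resampling and the network comparison test.

test_that("within-person centering decomposes exactly", {
  cfg <- dgp_config("common_cause", n_subjects = 300, n_waves = 4,
                    seed = 1)   # includes attrition
  pan <- simulate_panel(cfg)
  cw <- center_within(pan)
  # constant-over-waves subject has zero deviations
  flat <- pan
  flat$values[1, , ] <- rep(3.3, prod(dim(pan)[2:3]))
  flat$mask[1, , ] <- TRUE
  cw2 <- center_within(flat)
  expect_equal(unname(cw2$within$values[1, , ]),
               matrix(0, dim(pan)[2], dim(pan)[3]))
  # per-subject deviation means are exactly zero over observed waves
  dev_mean <- apply(cw$within$values, c(1, 3), mean, na.rm = TRUE)
  dev_mean[is.nan(dev_mean)] <- 0
  expect_lt(max(abs(dev_mean)), 1e-12)
  # reconstruction recovers every observed value (to floating-point ulp)
  rec <- cw$within$values
  for (j in seq_len(dim(pan)[3])) rec[, , j] <- rec[, , j] + cw$between[, j]
  obs <- pan$mask & cw$within$mask
  expect_lt(max(abs(rec[obs] - pan$values[obs])), 1e-12)
})

test_that("EM covariance matches sample moments and closed forms", {
  x <- rmvn(400, c(1, -1, 0), random_pd(3, 1))
  colnames(x) <- paste0("v", 1:3)
  em <- em_covariance(x)
  S <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  expect_lt(max(abs(em$cov - S)), 1e-10)
  expect_equal(em$iterations, 0L)
  # 20% MCAR holes: covariance recovered near the complete-data value
  x2 <- x
  big <- rmvn(2000, rep(0, 4), random_pd(4, 2))
  colnames(big) <- paste0("v", 1:4)
  S_big <- crossprod(sweep(big, 2, colMeans(big))) / nrow(big)
  holey <- big
  withr_seed(3, holey[matrix(stats::runif(length(big)) < 0.2, nrow(big))] <- NA)
  em2 <- em_covariance(holey)
  expect_lt(max(abs(em2$cov - S_big)), 0.05)
  # monotone bivariate pattern: regression-based closed form
  withr_seed(4, {
    z <- rmvn(1500, c(0, 0), matrix(c(1, 0.6, 0.6, 1.3), 2))
    miss <- sample(1500, 600)
  })
  z2 <- z; z2[miss, 2] <- NA
  colnames(z2) <- c("a", "b")
  em3 <- em_covariance(z2, tol = 1e-14, max_iter = 2000)
  # textbook monotone-MLE: moments of a from all cases; b via the
  # regression of b on a estimated from complete cases
  cc <- z2[stats::complete.cases(z2), ]
  nA <- nrow(z2)
  mA <- mean(z2[, "a"]); vA <- mean((z2[, "a"] - mA)^2)
  bhat <- stats::cov(cc[, "a"], cc[, "b"]) / stats::var(cc[, "a"])
  a0 <- mean(cc[, "b"]) - bhat * mean(cc[, "a"])
  mB <- a0 + bhat * mA
  ccn <- nrow(cc)
  Scc <- crossprod(sweep(cc, 2, colMeans(cc))) / ccn
  resid <- Scc["b", "b"] - Scc["a", "b"]^2 / Scc["a", "a"]
  covAB <- bhat * vA
  vB <- resid + bhat^2 * vA
  expect_equal(unname(em3$mean), c(mA, mB), tolerance = 1e-4)
  expect_equal(unname(em3$cov["a", "b"]), unname(covAB), tolerance = 1e-4)
  expect_equal(unname(em3$cov["b", "b"]), unname(vB), tolerance = 1e-4)
})

test_that("EBIC selection matches exhaustive enumeration on 4-node problems", {
  for (s in 1:10) {
    S <- random_pd(4, 100 + s)
    n <- c(200, 500, 1000)[1 + s %% 3]
    got <- estimate_ggm(S, n)
    want <- oracle_exhaustive_ggm(S, n)
    expect_true(identical(unname(got$adjacency), unname(want$adj)) ||
                  abs(got$ebic - want$ebic) < 1e-8)
  }
})

test_that("null and chain structures are recovered", {
  g0 <- estimate_ggm(diag(4), 1000)
  expect_equal(g0$n_edges, 0)
  K <- diag(4)
  K[1, 2] <- K[2, 1] <- K[2, 3] <- K[3, 2] <- K[3, 4] <- K[4, 3] <- -0.35
  withr_seed(7, {
    x <- rmvn(5000, rep(0, 4), solve(K))
  })
  colnames(x) <- paste0("v", 1:4)
  net <- pmutual:::fit_network(x, "ebic")
  truth <- K != 0; diag(truth) <- FALSE
  expect_identical(unname(net$adjacency), unname(truth))
  # partial correlations match -K_ij / sqrt(K_ii K_jj) of the refit
  pc <- -net$precision / sqrt(outer(diag(net$precision),
                                    diag(net$precision)))
  diag(pc) <- 0
  expect_lt(max(abs(net$weights - pc)), 1e-10)
  expect_error(estimate_ggm(matrix(c(1, 2, 2, 1), 2), 100),
               "positive definite")
})

test_that("centrality matches brute-force shortest-path computation", {
  # expected influence is a signed row sum
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["a", "c"] <- w["c", "a"] <- -0.2
  net <- structure(list(node_names = letters[1:3], weights = w, n = 100),
                   class = "ggm_network")
  ct <- centrality(net)
  expect_equal(ct$expected_influence[ct$node == "a"], 0.3)
  # 3-node path: middle node carries the one shortest path
  w2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w2["a", "b"] <- w2["b", "a"] <- 0.5
  w2["b", "c"] <- w2["c", "b"] <- 0.5
  net2 <- structure(list(node_names = letters[1:3], weights = w2, n = 100),
                    class = "ggm_network")
  ct2 <- centrality(net2)
  expect_equal(ct2$betweenness, c(0, 1, 0))
  # random 6-node weighted graphs vs Floyd-Warshall oracle
  for (s in 1:6) {
    withr_seed(200 + s, {
      w6 <- matrix(0, 6, 6)
      idx <- which(upper.tri(w6))
      on <- sample(idx, 8)
      w6[on] <- stats::runif(8, 0.1, 0.6) * sample(c(-1, 1), 8, TRUE)
      w6 <- w6 + t(w6)
    })
    dimnames(w6) <- list(paste0("n", 1:6), paste0("n", 1:6))
    net6 <- structure(list(node_names = paste0("n", 1:6), weights = w6,
                           n = 100), class = "ggm_network")
    ct6 <- centrality(net6)
    or6 <- oracle_centrality(w6)
    expect_equal(ct6$closeness, or6$closeness, tolerance = 1e-10)
    expect_equal(ct6$expected_influence, unname(or6$ei), tolerance = 1e-12)
  }
  # star graph: the hub has maximal closeness
  ws <- matrix(0, 5, 5); ws[1, 2:5] <- ws[2:5, 1] <- 0.4
  dimnames(ws) <- list(paste0("n", 1:5), paste0("n", 1:5))
  nets <- structure(list(node_names = paste0("n", 1:5), weights = ws,
                         n = 50), class = "ggm_network")
  cts <- centrality(nets)
  expect_equal(which.max(cts$closeness), 1L)
})

test_that("small-worldness behaves at its analytic limits", {
  full <- matrix(0.3, 5, 5); diag(full) <- 0
  sw <- small_worldness(full)
  expect_true(sw$defined)
  expect_gt(sw$swi, 0.8); expect_lt(sw$swi, 1.2)
  # rewired ring lattices are small-world
  hits <- vapply(1:20, function(s) {
    withr_seed(s, {
      g <- igraph::sample_smallworld(1, 50, 2, 0.1)
    })
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    adj[adj > 1] <- 1
    small_worldness(adj)$swi > 1
  }, logical(1))
  expect_gte(sum(hits), 19)
  expect_error(small_worldness(matrix(0, 5, 5)), "at least 1 edge")
  sparse <- matrix(0, 6, 6); sparse[1, 2] <- sparse[2, 1] <- 1
  expect_false(small_worldness(sparse)$defined)   # mean degree <= 1
})

test_that("edge bootstrap: reproducibility, strong-edge detection, coverage", {
  K <- diag(4)
  K[1, 2] <- K[2, 1] <- -0.4
  withr_seed(11, {
    x <- rmvn(2000, rep(0, 4), solve(K))
  })
  colnames(x) <- paste0("v", 1:4)
  b1 <- bootstrap_edges(x, B = 300, seed = 5, estimator = "saturated")
  b2 <- bootstrap_edges(x, B = 300, seed = 5, estimator = "saturated")
  expect_identical(b1$edge_ci, b2$edge_ci)
  ci <- b1$edge_ci[b1$edge_ci$edge == "v1--v2", ]
  expect_gt(ci$lower, 0)   # strong positive partial correlation
  # true-zero edge: CI covers 0 at ~95% over outer replications
  cover <- vapply(1:60, function(r) {
    withr_seed(500 + r, {
      xr <- rmvn(600, rep(0, 4), diag(4))
    })
    colnames(xr) <- paste0("v", 1:4)
    br <- bootstrap_edges(xr, B = 200, seed = r, estimator = "saturated")
    cr <- br$edge_ci[br$edge_ci$edge == "v1--v3", ]
    cr$lower <= 0 && cr$upper >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.87)
})

test_that("case-drop stability distinguishes signal from noise", {
  # strong, near-deterministic network
  K <- diag(6)
  for (i in 1:5) K[i, i + 1] <- K[i + 1, i] <- -0.4
  withr_seed(12, {
    xs <- rmvn(20000, rep(0, 6), solve(K))
  })
  colnames(xs) <- paste0("v", 1:6)
  cs_hi <- case_drop_cs(xs, B = 60, seed = 3, estimator = "saturated")
  expect_gte(cs_hi$cs, 0.70)
  expect_identical(cs_hi$label, "excellent")
  # pure noise (small n so subsampled profiles decorrelate)
  withr_seed(13, {
    xn <- matrix(stats::rnorm(100 * 6), 100, 6)
  })
  colnames(xn) <- paste0("v", 1:6)
  cs_lo <- case_drop_cs(xn, B = 60, seed = 4, estimator = "saturated")
  expect_lte(cs_lo$cs, 0.25)
  # monotone degradation as noise increases
  mid <- 0.5 * xs[1:2000, ] + 0.5 * matrix(stats::rnorm(2000 * 6), 2000, 6)
  colnames(mid) <- paste0("v", 1:6)
  cs_mid <- case_drop_cs(mid, B = 60, seed = 5, estimator = "saturated")
  expect_lte(cs_lo$cs, cs_mid$cs + 1e-12)
  expect_lte(cs_mid$cs, cs_hi$cs + 1e-12)
})

test_that("NCT degenerate and structural cases", {
  withr_seed(14, {
    x <- rmvn(400, rep(0, 5), random_pd(5, 21))
  })
  colnames(x) <- paste0("v", 1:5)
  r <- nct(x, x, n_perm = 200, seed = 6)
  expect_equal(r$M, 0)
  expect_equal(r$S, 0)
  expect_equal(r$p_M, 1)
  y <- x; colnames(y) <- paste0("w", 1:5)
  expect_error(nct(x, y), "node sets")
  # reproducible given seed
  withr_seed(15, {
    xb <- rmvn(400, rep(0, 5), random_pd(5, 22))
  })
  colnames(xb) <- paste0("v", 1:5)
  r1 <- nct(x, xb, n_perm = 200, seed = 7)
  r2 <- nct(x, xb, n_perm = 200, seed = 7)
  expect_identical(r1$p_M, r2$p_M)
  expect_identical(r1$p_S, r2$p_S)
  # paired mode runs and respects alignment requirements
  rp <- nct(x, xb, n_perm = 100, paired = TRUE, seed = 8)
  expect_true(rp$paired)
  expect_error(nct(x, xb[1:100, ], paired = TRUE), "aligned")
})

test_that("between-person network on within-centered data is near-empty", {
  cfg <- dgp_config("mutualism", n_subjects = 5000, n_waves = 6,
                    attrition_hazard = 0, seed = 16)
  pan <- simulate_panel(cfg)
  cw <- center_within(pan)
  # person means of deviations are ~0 by construction; a "between" network
  # built from them carries no structure
  bet_dev <- apply(cw$within$values, c(1, 3), mean, na.rm = TRUE)
  expect_lt(max(abs(bet_dev)), 1e-10)
})

test_that("node-order permutation leaves network statistics invariant", {
  S <- random_pd(5, 31)
  colnames(S) <- rownames(S) <- paste0("v", 1:5)
  net <- estimate_ggm(S, 800)
  perm <- c(3, 1, 5, 2, 4)
  net_p <- estimate_ggm(S[perm, perm], 800)
  expect_equal(unname(net_p$weights),
               unname(net$weights[perm, perm]), tolerance = 1e-9)
  sw <- small_worldness(net); sw_p <- small_worldness(net_p)
  expect_equal(sw$swi, sw_p$swi, tolerance = 1e-12)
  ct <- centrality(net); ct_p <- centrality(net_p)
  expect_equal(ct$expected_influence[perm], ct_p$expected_influence,
               tolerance = 1e-12)
})
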