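# Bifactor spec construction, the index set, and endpoint loading tests.

count_free_beta <- function(spec) {
  sum(spec$beta$label != "")
}

test_that("structural path bookkeeping for both variants", {
  W <- 5
  ar <- build_bifactor_spec(14:(13 + W))
  cl <- build_bifactor_spec(14:(13 + W), variant = "cross_lagged")
  expect_equal(count_free_beta(ar), 3 * (W - 1))
  expect_equal(count_free_beta(cl), 9 * (W - 1))
  # identification convention: all factor variances fixed at 1, means 0
  expect_true(all(diag(ar$psi$value) == 1))
  expect_false(any(ar$psi$label != ""))
  expect_true(all(ar$alpha$value == 0) && !any(nzchar(ar$alpha$label)))
  # degenerate single-wave call: plain cross-sectional bifactor
  cs <- build_bifactor_spec(14)
  expect_equal(count_free_beta(cs), 0)
  expect_equal(length(cs$lat), 3)
  expect_error(build_bifactor_spec(14:15, domains = c(gad = "int")),
               "assigned")
})

test_that("bifactor index arithmetic matches the independent oracle exactly", {
  # 6 indicators, lg .6, ls .4, two 3-indicator subscales, unit variances
  lg <- rep(0.6, 6); ls <- rep(0.4, 6)
  domains <- rep(c("int", "ext"), each = 3)
  theta <- 1 - lg^2 - ls^2
  got <- pmutual:::bifactor_indices_from_loadings(lg, ls, domains, theta)
  want <- oracle_bifactor_indices(lg, ls, domains, theta)
  for (f in c("general", "int", "ext")) {
    row <- got[got$factor == f, ]
    for (col in c("ecv", "ecv_ss", "omega", "omega_h", "relative_omega", "H")) {
      expect_equal(row[[col]], unname(want[[f]][col]), tolerance = 1e-12,
                   label = paste(f, col))
    }
  }
  # hand-checked anchor: omega_h = (6*.6)^2 / ((3.6)^2 + 2*(1.2)^2 + sum(theta))
  expect_equal(got$omega_h[got$factor == "general"],
               3.6^2 / (3.6^2 + 2 * 1.2^2 + sum(theta)), tolerance = 1e-12)
})

test_that("index set invariants hold on random admissible configurations", {
  for (s in 1:20) {
    withr_seed(s, {
      k <- sample(5:8, 1)
      domains <- sample(c("int", "ext"), k, replace = TRUE)
      while (length(unique(domains)) < 2 || min(table(domains)) < 2) {
        domains <- sample(c("int", "ext"), k, replace = TRUE)
      }
      lg <- runif(k, 0.2, 0.7)
      ls <- runif(k, 0.1, pmin(0.7, sqrt(0.95 - lg^2)))
      theta <- 1 - lg^2 - ls^2
    })
    idx <- pmutual:::bifactor_indices_from_loadings(lg, ls, domains, theta)
    num <- unlist(idx[, c("ecv", "ecv_ss", "omega", "omega_h",
                          "relative_omega", "H")])
    expect_true(all(num >= -1e-12 & num <= 1 + 1e-12))
    expect_equal(sum(idx$ecv), 1, tolerance = 1e-10)
    expect_equal(idx$relative_omega, idx$omega_h / idx$omega,
                 tolerance = 1e-10)
    expect_true(all(idx$omega_h <= idx$omega + 1e-12))
  }
})

test_that("degenerate loading patterns hit the documented limits", {
  lg <- rep(0.6, 6); ls <- rep(0, 6)
  domains <- rep(c("int", "ext"), each = 3)
  idx <- pmutual:::bifactor_indices_from_loadings(lg, ls, domains, 1 - lg^2)
  expect_equal(idx$ecv[idx$factor == "general"], 1)
  expect_equal(idx$omega_h[idx$factor != "general"], c(0, 0))
  # standardized loading at 1 flags H as undefined
  idx2 <- pmutual:::bifactor_indices_from_loadings(
    c(1, 0.5, 0.5, 0.5, 0.5, 0.5), ls, domains, rep(0.1, 6))
  expect_true(is.na(idx2$H[idx2$factor == "general"]))
  expect_match(idx2$flag[idx2$factor == "general"], "loading")
})

test_that("fitted indices are invariant to indicator order and nesting holds", {
  cfg <- dgp_config("common_cause", n_subjects = 800, n_waves = 3,
                    attrition_hazard = 0, seed = 41)
  pan <- simulate_panel(cfg)
  x <- panel_wide_matrix(pan)
  spec <- build_bifactor_spec(pan$waves, pan$variables)
  fit <- sem_fit(spec, x, se = FALSE)
  idx <- compute_bifactor_indices(fit, 15)
  perm <- c("odd", "gad", "subuse", "mdd", "cdaspd", "adhd")
  spec2 <- build_bifactor_spec(pan$waves, perm)
  fit2 <- sem_fit(spec2, x, se = FALSE)
  idx2 <- compute_bifactor_indices(fit2, 15)
  expect_equal(idx[idx$factor == "general", "ecv"],
               idx2[idx2$factor == "general", "ecv"], tolerance = 1e-4)
  expect_equal(idx[idx$factor == "general", "omega_h"],
               idx2[idx2$factor == "general", "omega_h"], tolerance = 1e-4)
  # the cross-lagged variant never fits worse than the autoregressive one
  spec_cl <- build_bifactor_spec(pan$waves, pan$variables,
                                 variant = "cross_lagged")
  fit_cl <- sem_fit(spec_cl, x, se = FALSE, start = fit$estimates)
  expect_gte(fit_cl$loglik, fit$loglik - 1e-4)
})

test_that("fitted ECV tracks the generator-implied value", {
  cfg <- dgp_config("common_cause", n_subjects = 2000, n_waves = 3,
                    attrition_hazard = 0, seed = 42)
  pan <- simulate_panel(cfg)
  tr <- attr(pan, "truth")
  pop <- pmutual:::bifactor_indices_from_loadings(
    tr$lambda_g, tr$lambda_s, cfg$domains, tr$theta)
  fit <- sem_fit(build_bifactor_spec(pan$waves, pan$variables),
                 panel_wide_matrix(pan), se = FALSE)
  for (w in pan$waves) {
    idx <- compute_bifactor_indices(fit, w)
    expect_lt(abs(idx$ecv[idx$factor == "general"] -
                    pop$ecv[pop$factor == "general"]), 0.05)
  }
})

test_that("endpoint Wald tests detect rising loadings and stay quiet when constant", {
  # constant-loading generator: no rejection expected at typical seeds
  cfg0 <- dgp_config("common_cause", n_subjects = 1200, n_waves = 4,
                     attrition_hazard = 0, seed = 43)
  pan0 <- simulate_panel(cfg0)
  fit0 <- sem_fit(build_bifactor_spec(pan0$waves, pan0$variables),
                  panel_wide_matrix(pan0))
  w0 <- endpoint_loading_wald(fit0, "mdd")
  expect_gt(w0$test$p, 0.01)
  # constrained equality reproduces a zero statistic
  est <- fit0$estimates
  t0 <- sem_wald(fit0, list(function(th) th[["lg_mdd_17"]] -
                              est[["lg_mdd_17"]]))
  expect_lt(t0$statistic, 1e-10)
  # rising general loading: inject growth on the last wave and expect a
  # positive-direction rejection
  pan1 <- simulate_panel(cfg0)
  x1 <- panel_wide_matrix(pan1)
  tr <- attr(pan1, "truth")
  x1[, "mdd.17"] <- x1[, "mdd.17"] + 0.5 * tr$factors$p[, 4]
  fit1 <- sem_fit(build_bifactor_spec(pan1$waves, pan1$variables), x1)
  w1 <- endpoint_loading_wald(fit1, "mdd")
  expect_lt(w1$test$p, 0.05)
  expect_equal(w1$direction, 1)
})
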