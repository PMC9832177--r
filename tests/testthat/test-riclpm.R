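# RI-CLPM family: spec bookkeeping, CLPM equivalence, recovery, and the
# between/within conflation signature.

test_that("variant bookkeeping: cross-lags and RI constraints", {
  W <- 5; waves <- 14:18
  base <- build_riclpm_spec(waves, "baseline")
  bid <- build_riclpm_spec(waves, "bidirectional")
  clpm <- build_riclpm_spec(waves, "clpm")
  n_cl <- function(s) sum(grepl("^c_(ie|ei)_", s$beta$label))
  expect_equal(n_cl(base), 0)
  expect_equal(n_cl(bid), 2 * (W - 1))
  expect_equal(n_cl(build_riclpm_spec(waves, "int_to_ext")), W - 1)
  # clpm fixes exactly the 2 RI variances + 1 covariance relative to
  # bidirectional
  expect_equal(n_free_params(bid) - n_free_params(clpm), 3)
  expect_true(all(clpm$psi$value[c("ri_int", "ri_ext"),
                                 c("ri_int", "ri_ext")] == 0))
  # 8 waves reproduces the full transition layout: 7 x (2 AR + 2 CL)
  bid8 <- build_riclpm_spec(14:21, "bidirectional")
  expect_equal(sum(bid8$beta$label != ""), 7 * 4)
  expect_error(build_riclpm_spec(14:15), "at least 3 waves")
})

test_that("clpm variant equals an independently specified CLPM", {
  pan <- gen_riclpm_panel(800, 14:17, c_ie = 0.15, c_ei = 0.1, seed = 51)
  x <- panel_wide_matrix(pan)
  f1 <- sem_fit(build_riclpm_spec(14:17, "clpm"), x, se = FALSE,
                baseline = FALSE)
  # Independent construction: observed-variable cross-lagged model via
  # phantom latents (one per observed score, loading 1, zero residual).
  waves <- 14:17
  obs <- paste0(rep(c("int", "ext"), 4), ".", rep(waves, each = 2))
  lat <- paste0("f_", obs)
  k <- length(obs)
  lam <- list(value = diag(1, k), label = matrix("", k, k))
  psi_l <- matrix("", k, k, dimnames = list(lat, lat))
  psi_v <- matrix(0, k, k, dimnames = list(lat, lat))
  beta_l <- matrix("", k, k, dimnames = list(lat, lat))
  for (w in seq_along(waves)) {
    i1 <- 2 * w - 1; i2 <- 2 * w
    psi_l[i1, i1] <- paste0("vi", w); psi_l[i2, i2] <- paste0("ve", w)
    psi_l[i1, i2] <- psi_l[i2, i1] <- paste0("cv", w)
    psi_v[i1, i1] <- psi_v[i2, i2] <- 1
    if (w > 1) {
      beta_l[i1, i1 - 2] <- paste0("aii", w)
      beta_l[i2, i2 - 2] <- paste0("aee", w)
      beta_l[i1, i2 - 2] <- paste0("aie", w)
      beta_l[i2, i1 - 2] <- paste0("aei", w)
    }
  }
  spec2 <- sem_spec(obs, lat, lam,
                    beta = list(value = matrix(0, k, k), label = beta_l),
                    psi = list(value = psi_v, label = psi_l),
                    theta = list(value = matrix(0, k, k),
                                 label = matrix("", k, k)))
  f2 <- sem_fit(spec2, x, se = FALSE, baseline = FALSE)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-5)
  # matching structural coefficients (CLPM autoregressions/cross-lags)
  expect_equal(unname(f1$estimates[paste0("a_int_", 15:17)]),
               unname(f2$estimates[paste0("aii", 2:4)]), tolerance = 1e-4)
  expect_equal(unname(f1$estimates[paste0("c_ei_", 15:17)]),
               unname(f2$estimates[paste0("aie", 2:4)]), tolerance = 1e-4)
})

test_that("RI variances and correlation are recovered", {
  errs <- t(vapply(1:8, function(s) {
    pan <- gen_riclpm_panel(2000, 14:18, c_ie = 0.1, c_ei = 0.1,
                            ri_var = c(4, 9), ri_cor = 0.5, seed = 60 + s)
    fit <- sem_fit(build_riclpm_spec(14:18, "bidirectional"),
                   panel_wide_matrix(pan), se = FALSE, baseline = FALSE)
    est <- extract_riclpm_estimates(fit)
    c(vi = est$ri$var_int, ve = est$ri$var_ext, r = est$ri$correlation)
  }, c(vi = 0, ve = 0, r = 0)))
  expect_lt(abs(stats::median(errs[, "vi"]) - 4) / 4, 0.10)
  expect_lt(abs(stats::median(errs[, "ve"]) - 9) / 9, 0.10)
  expect_lt(abs(stats::median(errs[, "r"]) - 0.5), 0.07)
})

test_that("independent within-person innovations give near-zero within-time correlations", {
  pan <- gen_riclpm_panel(10000, 14:18, wcov = 0, ri_cor = 0.3, seed = 70)
  fit <- sem_fit(build_riclpm_spec(14:18, "bidirectional"),
                 panel_wide_matrix(pan), se = FALSE, baseline = FALSE)
  est <- extract_riclpm_estimates(fit)
  # innovation residual correlations (waves 2+) vanish; the wave-1
  # exogenous-block correlation is only weakly separated from the RI
  # covariance and gets a looser band
  expect_lt(max(abs(est$within_time_cor[-1])), 0.05)
  expect_lt(abs(est$within_time_cor[1]), 0.10)
})

test_that("CLPM conflates between-person variance into autoregressions", {
  # Directional signature over seeds: fitting the CLPM to RI-CLPM data
  # inflates autoregressive estimates relative to the RI-CLPM fit.
  wins <- vapply(1:10, function(s) {
    pan <- gen_riclpm_panel(700, 14:17, ri_var = c(4, 9), seed = 80 + s)
    x <- panel_wide_matrix(pan)
    f_ri <- sem_fit(build_riclpm_spec(14:17, "bidirectional"), x,
                    se = FALSE, baseline = FALSE)
    f_cl <- sem_fit(build_riclpm_spec(14:17, "clpm"), x,
                    se = FALSE, baseline = FALSE)
    ar_lab <- c(paste0("a_int_", 15:17), paste0("a_ext_", 15:17))
    mean(f_cl$estimates[ar_lab]) > mean(f_ri$estimates[ar_lab])
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("family comparison behaves under null and directional generators", {
  # null: no cross-lags, moderate RI variance -> baseline not rejected
  # against bidirectional
  pan0 <- gen_riclpm_panel(900, 14:18, seed = 91)
  cmp0 <- compare_riclpm_family(panel_wide_matrix(pan0), waves = 14:18)
  expect_gt(cmp0$lrts$baseline_vs_bidirectional$p, 0.05)
  expect_identical(cmp0$best, "baseline")
  # boundary test: strong RI variance is detected against the CLPM
  expect_lt(cmp0$boundary_test$p, 0.001)
  # directional: INT -> EXT lags only
  pan1 <- gen_riclpm_panel(1500, 14:18, c_ie = 0.2, c_ei = 0, seed = 92)
  cmp1 <- compare_riclpm_family(panel_wide_matrix(pan1), waves = 14:18)
  aic <- stats::setNames(cmp1$table$aic, cmp1$table$model)
  expect_lt(aic[["int_to_ext"]], aic[["ext_to_int"]])
  # identical-data degenerate comparison
  expect_equal(aic[["baseline"]] - aic[["baseline"]], 0)
})
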