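# Synthetic panel generator: determinism, implied moments, attrition,
# discretization, and the mutualism/differentiation coupling schedules.

test_that("identical configs produce identical panels", {
  cfg <- dgp_config("mutualism", n_subjects = 200, n_waves = 4, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$mask, p2$mask)
  p3 <- simulate_panel(dgp_config("mutualism", n_subjects = 200, n_waves = 4,
                                  seed = 100))
  expect_false(identical(p1$values, p3$values))
})

test_that("common-cause wave-1 covariance matches the implied moments", {
  cfg <- dgp_config("common_cause", n_subjects = 50000, n_waves = 2,
                    attrition_hazard = 0, seed = 5)
  pan <- simulate_panel(cfg)
  S <- stats::cov(panel_wave_matrix(pan, 14)) * (50000 - 1) / 50000
  implied <- attr(pan, "truth")$implied_wave_cov
  expect_lt(max(abs(S - implied)), 0.02)
})

test_that("decoupled VAR limit has no lag-1 cross-domain correlation", {
  cfg <- dgp_config("mutualism", n_subjects = 50000, n_waves = 3,
                    coupling_start = 0, coupling_end = 0,
                    within_domain_coupling = 0,
                    innovation_cov = diag(6),
                    baseline_cor = c(within = 0, cross = 0),
                    attrition_hazard = 0, seed = 6)
  pan <- simulate_panel(cfg)
  y1 <- panel_wave_matrix(pan, 14); y2 <- panel_wave_matrix(pan, 15)
  dom <- c("int", "int", "ext", "ext", "ext", "ext")
  cc <- stats::cor(y2, y1)[dom == "int", dom == "ext"]
  expect_lt(max(abs(cc)), 0.02)
})

test_that("explosive VAR configurations are rejected at validation", {
  expect_error(
    dgp_config("mutualism", n_subjects = 100, n_waves = 4,
               within_ar = 0.8, coupling_end = 0.5, seed = 1),
    "explosive|spectral")
})

test_that("attrition follows the survival product and is monotone", {
  cfg <- dgp_config("common_cause", n_subjects = 10000, n_waves = 8,
                    attrition_hazard = 0, seed = 7)
  pan <- simulate_panel(cfg)
  expect_identical(apply_attrition(pan, 0)$mask, pan$mask)
  withr_seed(8, {
    gone <- apply_attrition(pan, c(1, rep(0, 6)))
  })
  expect_true(all(gone$mask[, 1, ]))
  expect_false(any(gone$mask[, 2:8, ]))
  withr_seed(9, {
    att <- apply_attrition(pan, 0.13)
  })
  expect_equal(mean(att$mask[, 8, 1]), 0.87^7, tolerance = 0.03)
  # monotone: once missing, always missing
  obs <- att$mask[, , 1]
  expect_true(all(apply(obs, 1, function(r) all(diff(r) <= 0) ||
                          all(r == cummax(r)))))
  expect_true(all(att$mask[, 1, ]))
})

test_that("MAR attrition raises dropout among high scorers", {
  cfg <- dgp_config("common_cause", n_subjects = 8000, n_waves = 3,
                    attrition_hazard = 0, seed = 10)
  pan <- simulate_panel(cfg)
  withr_seed(11, {
    mar <- apply_attrition(pan, 0.3, mar_on = "mdd", mar_strength = 1.5)
  })
  hi <- pan$values[, 1, 2] > stats::median(pan$values[, 1, 2])
  drop2 <- !mar$mask[, 2, 1]
  expect_gt(mean(drop2[hi]), mean(drop2[!hi]) + 0.05)
})

test_that("Likert discretization is monotone and rank-preserving", {
  cfg <- dgp_config("common_cause", n_subjects = 5000, n_waves = 2,
                    attrition_hazard = 0, seed = 12)
  pan <- simulate_panel(cfg)
  disc <- discretize_to_likert(pan, seq(-2, 2, length.out = 7))
  expect_true(all(disc$values %in% 0:7))
  expect_equal(unname(disc$values[, 1, 1][pan$values[, 1, 1] < -2]),
               rep(0, sum(pan$values[, 1, 1] < -2)))
  rho <- stats::cor(pan$values[, 1, 1], disc$values[, 1, 1],
                    method = "spearman")
  expect_gt(rho, 0.95)
  # degenerate all-infinite threshold spec collapses to one category
  one <- discretize_to_likert(pan, c(-Inf, Inf))
  expect_true(all(one$values == 0))
  expect_error(discretize_to_likert(pan, c(1, 1, 2)), "strictly increasing")
})

test_that("mutualism couplings rise and differentiation couplings fall", {
  cfgm <- dgp_config("mutualism", n_subjects = 20000, n_waves = 8,
                     attrition_hazard = 0, seed = 13)
  cfgd <- dgp_config("differentiation", n_subjects = 20000, n_waves = 8,
                     attrition_hazard = 0, seed = 13)
  dom <- c("int", "int", "ext", "ext", "ext", "ext")
  cross_traj <- function(pan) {
    vapply(pan$waves, function(w) {
      C <- stats::cor(panel_wave_matrix(pan, w))
      mean(C[dom == "int", dom == "ext"])
    }, 0)
  }
  tm <- cross_traj(simulate_panel(cfgm))
  td <- cross_traj(simulate_panel(cfgd))
  # trend over the second half is clearly up (mutualism) / down (differentiation)
  expect_gt(tm[8], tm[2] + 0.1)
  expect_lt(td[8], td[2] - 0.1)
  # ground truth transition matrices follow the configured schedule
  Am <- attr(simulate_panel(cfgm), "truth")$A
  expect_lt(max(abs(Am[[1]][1, 3:6])), 1e-12)
  expect_equal(sum(Am[[7]][1, 3:6]), 0.3, tolerance = 1e-10)
})

test_that("MCAR attrition leaves covariance estimable without bias", {
  cfg <- dgp_config("common_cause", n_subjects = 4000, n_waves = 4,
                    attrition_hazard = 0, seed = 14)
  pan <- simulate_panel(cfg)
  full <- panel_wide_matrix(pan)
  withr_seed(15, {
    att <- apply_attrition(pan, 0.15)
  })
  em <- em_covariance(panel_wide_matrix(att))
  S_full <- stats::cov(full) * (4000 - 1) / 4000
  expect_lt(max(abs(em$cov - S_full)), 0.12)
  expect_lt(max(abs(em$cov - S_full)) / max(abs(S_full)), 0.12)
})

test_that("dgp configs round-trip through YAML and JSON", {
  cfg <- dgp_config("differentiation", n_subjects = 50, n_waves = 5,
                    coupling_start = 0.25, coupling_end = 0.05, seed = 17)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    dgp_config_to_file(cfg, f)
    back <- dgp_config_from_file(f)
    expect_equal(back$coupling_start, 0.25)
    expect_equal(back$innovation_cov, cfg$innovation_cov,
                 ignore_attr = TRUE)
    expect_identical(simulate_panel(back)$values, simulate_panel(cfg)$values)
  }
})
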