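# Longitudinal bifactor models: specification builders, the bifactor
# strength/reliability index set, and endpoint loading equality tests on the
# general factor.

#' Build a longitudinal bifactor specification
#'
#' Per wave, every indicator loads on a general factor (p) and on its domain
#' factor (internalizing or externalizing); the three factors are mutually
#' orthogonal within wave. Factors carry lag-1 autoregressions; the
#' cross-lagged variant adds all six lag-1 cross-paths among p, INT and EXT.
#' Identification follows the standardized-factor convention: all factor
#' (residual) variances fixed to 1, all factor means 0, loadings free per
#' wave.
#'
#' @param waves Integer age labels (e.g. `14:21`); a single wave yields the
#'   plain cross-sectional bifactor with no structural paths.
#' @param indicators Character vector of composite names.
#' @param domains Named map indicator -> `"int"`/`"ext"` (defaults to the
#'   standard assignment: gad, mdd internalizing; the rest externalizing).
#' @param variant `"autoregressive"` or `"cross_lagged"`.
#' @param lag1_residual_cor Allow lag-1 autocovariances of the same
#'   indicator's residuals (default `FALSE`).
#' @return A [sem_spec] over observed variables named `<indicator>.<age>`
#'   (the [panel_wide_matrix] naming), carrying an `invariance` attribute
#'   with metric (loadings) and scalar (intercepts) cross-wave groups.
#' @export
build_bifactor_spec <- function(waves, indicators = default_variables,
                                domains = default_domains[indicators],
                                variant = c("autoregressive", "cross_lagged"),
                                lag1_residual_cor = FALSE) {
  variant <- match.arg(variant)
  waves <- as.integer(waves)
  W <- length(waves)
  k <- length(indicators)
  domains <- domains[indicators]
  if (any(is.na(domains)) || !all(domains %in% c("int", "ext"))) {
    stop("every indicator must be assigned to 'int' or 'ext'")
  }
  obs <- paste0(rep(indicators, times = W), ".", rep(waves, each = k))
  factors <- c("p", "int", "ext")
  lat <- paste0(rep(factors, times = W), ".", rep(waves, each = 3))
  lam_v <- matrix(0, length(obs), length(lat),
                  dimnames = list(obs, lat))
  lam_l <- matrix("", length(obs), length(lat), dimnames = list(obs, lat))
  th_v <- diag(0.5, length(obs)); dimnames(th_v) <- list(obs, obs)
  th_l <- matrix("", length(obs), length(obs), dimnames = list(obs, obs))
  for (w in seq_len(W)) for (j in seq_len(k)) {
    ov <- paste0(indicators[j], ".", waves[w])
    lam_l[ov, paste0("p.", waves[w])] <- paste0("lg_", indicators[j], "_", waves[w])
    lam_l[ov, paste0(domains[j], ".", waves[w])] <-
      paste0("ls_", indicators[j], "_", waves[w])
    th_l[ov, ov] <- paste0("th_", indicators[j], "_", waves[w])
    if (lag1_residual_cor && w > 1) {
      prev <- paste0(indicators[j], ".", waves[w - 1])
      th_l[ov, prev] <- th_l[prev, ov] <-
        paste0("thcov_", indicators[j], "_", waves[w])
    }
  }
  # Factor (residual) variances all fixed to 1; orthogonal within wave.
  psi_v <- diag(1, length(lat)); dimnames(psi_v) <- list(lat, lat)
  psi_l <- matrix("", length(lat), length(lat), dimnames = list(lat, lat))
  beta_v <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  beta_l <- matrix("", length(lat), length(lat), dimnames = list(lat, lat))
  if (W > 1) {
    for (w in 2:W) {
      a <- waves[w]; b <- waves[w - 1]
      for (f in factors) {
        beta_l[paste0(f, ".", a), paste0(f, ".", b)] <- paste0("ar_", f, "_", a)
      }
      if (variant == "cross_lagged") {
        for (f in factors) for (g in setdiff(factors, f)) {
          beta_l[paste0(f, ".", a), paste0(g, ".", b)] <-
            paste0("cl_", g, "_", f, "_", a)   # g at b -> f at a
        }
      }
    }
  }
  nu_l <- paste0("nu_", rep(indicators, times = W), "_", rep(waves, each = k))
  spec <- sem_spec(obs, lat,
                   lambda = list(value = lam_v, label = lam_l),
                   beta = list(value = beta_v, label = beta_l),
                   psi = list(value = psi_v, label = psi_l),
                   theta = list(value = th_v, label = th_l),
                   nu = list(value = rep(0, length(obs)), label = nu_l))
  metric <- c(
    lapply(indicators, function(v) paste0("lg_", v, "_", waves)),
    lapply(indicators, function(v) paste0("ls_", v, "_", waves)))
  scalar <- lapply(indicators, function(v) paste0("nu_", v, "_", waves))
  later <- if (W > 1) {
    as.vector(outer(factors, waves[-1], function(f, w) paste0(f, ".", w)))
  } else character(0)
  # Under equality constraints the factor scale must move to the factor
  # (residual) variances / latent means at waves 2+, as in the standard
  # longitudinal-invariance parameterization.
  attr(spec, "invariance") <- list(metric = metric, scalar = scalar,
                                   metric_free_var = later,
                                   scalar_free_mean = later)
  attr(spec, "bifactor") <- list(waves = waves, indicators = indicators,
                                 domains = domains, variant = variant)
  spec
}

#' Bifactor strength, reliability and replicability indices for one wave
#'
#' Computes, from the completely standardized loadings of a fitted
#' longitudinal (or cross-sectional) bifactor model at one wave:
#' explained common variance (global ECV, summing to 1 across factors, and
#' the subscale-relative ECV_SS), omega total and subscale omega, omega
#' hierarchical and hierarchical-subscale, relative omega, and the H
#' construct-replicability index. Total-score variance uses the
#' model-implied decomposition `(sum lg)^2 + sum_s (sum ls)^2 + sum theta`.
#'
#' @param fit A converged `sem_fit` of a spec built by
#'   [build_bifactor_spec()].
#' @param wave Age label.
#' @return A data frame of class `bifactor_indices`: one row per factor
#'   (general + each specific) with columns `ecv`, `ecv_ss`, `omega`,
#'   `omega_h`, `relative_omega`, `H` and `flag`.
#' @export
compute_bifactor_indices <- function(fit, wave) {
  meta <- attr(fit$spec, "bifactor")
  if (is.null(meta)) stop("fit is not a bifactor model")
  if (!wave %in% meta$waves) stop("wave ", wave, " not in the fitted model")
  if (!fit$converged) stop("fit did not converge")
  ind <- meta$indicators
  obs <- paste0(ind, ".", wave)
  lam <- fit$std$lambda[obs, , drop = FALSE]
  lg <- lam[, paste0("p.", wave)]
  doms <- sort(unique(meta$domains))
  ls_all <- numeric(length(ind)); names(ls_all) <- ind
  for (d in doms) {
    idx <- which(meta$domains == d)
    ls_all[idx] <- lam[idx, paste0(d, ".", wave)]
  }
  th <- pmax(1 - lg^2 - ls_all^2, 0)
  bifactor_indices_from_loadings(lg, ls_all, meta$domains, th, wave = wave)
}

# Pure arithmetic core, shared by compute_bifactor_indices and usable on raw
# loading configurations.
bifactor_indices_from_loadings <- function(lg, ls, domains, theta,
                                           wave = NA_integer_) {
  doms <- sort(unique(domains))
  sum_lg2 <- sum(lg^2)
  sum_ls2_by <- vapply(doms, function(d) sum(ls[domains == d]^2), 0)
  common <- sum_lg2 + sum(sum_ls2_by)
  var_total <- sum(lg)^2 + sum(vapply(doms, function(d)
    sum(ls[domains == d])^2, 0)) + sum(theta)
  H_of <- function(l) {
    if (any(abs(l) >= 1)) return(NA_real_)
    s <- sum(l^2 / (1 - l^2))
    s / (1 + s)
  }
  rows <- list()
  # General factor
  omega <- (sum(lg)^2 + sum(vapply(doms, function(d)
    sum(ls[domains == d])^2, 0))) / var_total
  omega_h <- sum(lg)^2 / var_total
  rows$general <- data.frame(
    wave = wave, factor = "general",
    ecv = sum_lg2 / common, ecv_ss = sum_lg2 / common,
    omega = omega, omega_h = omega_h,
    relative_omega = omega_h / omega,
    H = H_of(lg),
    flag = if (any(abs(lg) >= 1)) "loading>=1" else "",
    stringsAsFactors = FALSE)
  for (d in doms) {
    idx <- which(domains == d)
    sub_den <- sum(lg[idx])^2 + sum(ls[idx])^2 + sum(theta[idx])
    omega_s <- (sum(lg[idx])^2 + sum(ls[idx])^2) / sub_den
    omega_hs <- sum(ls[idx])^2 / sub_den
    rows[[d]] <- data.frame(
      wave = wave, factor = d,
      ecv = sum_ls2_by[[d]] / common,
      ecv_ss = sum(ls[idx]^2) / (sum(lg[idx]^2) + sum(ls[idx]^2)),
      omega = omega_s, omega_h = omega_hs,
      relative_omega = omega_hs / omega_s,
      H = H_of(ls[idx]),
      flag = if (any(abs(ls[idx]) >= 1)) "loading>=1" else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bifactor_indices", "data.frame")
  out
}

#' Bifactor index trajectories across all fitted waves
#'
#' @param fit A converged bifactor `sem_fit`.
#' @param csv_path Optional CSV output (one row per wave x factor).
#' @return A `bifactor_indices` data frame over all waves.
#' @export
bifactor_index_table <- function(fit, csv_path = NULL) {
  meta <- attr(fit$spec, "bifactor")
  out <- do.call(rbind, lapply(meta$waves, function(w)
    compute_bifactor_indices(fit, w)))
  class(out) <- c("bifactor_indices", "data.frame")
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Endpoint equality Wald test for a general-factor loading
#'
#' Single-df Wald test that an indicator's loading on the general factor is
#' equal at the first and last fitted wave, reported together with the
#' direction of the difference (positive = loading grew). By default the
#' comparison is on completely standardized loadings (delta method), which
#' are comparable across waves regardless of how factor scale is set; with
#' `standardized = FALSE` the raw loading labels are compared directly.
#'
#' @param fit A converged bifactor `sem_fit` with standard errors.
#' @param indicator Indicator name.
#' @param factor Factor whose loadings are compared (default the general
#'   factor `"p"`; `"int"`/`"ext"` test the domain loading).
#' @param waves Length-2 vector of age labels (default first and last).
#' @param standardized Compare standardized loadings (default `TRUE`).
#' @return List with `test` (a `sem_test`), `direction` (sign of
#'   last-minus-first), and the two loading estimates compared.
#' @export
endpoint_loading_wald <- function(fit, indicator, factor = "p", waves = NULL,
                                  standardized = TRUE) {
  meta <- attr(fit$spec, "bifactor")
  if (is.null(meta)) stop("fit is not a bifactor model")
  waves <- waves %||% range(meta$waves)
  if (!all(waves %in% meta$waves)) stop("requested waves not in the model")
  fct <- if (factor == "p") "p" else factor
  if (standardized) {
    spec <- fit$spec
    std_at <- function(theta, w) {
      mats <- spec_matrices(spec, theta)
      imp <- implied_moments(mats)
      i <- match(paste0(indicator, ".", w), spec$obs)
      fj <- if (factor == "p") paste0("p.", w) else
        paste0(meta$domains[[indicator]], ".", w)
      j <- match(fj, spec$lat)
      mats$lambda[i, j] * sqrt(imp$E[j, j]) / sqrt(imp$sigma[i, i])
    }
    con <- function(theta) std_at(theta, waves[2]) - std_at(theta, waves[1])
    test <- sem_wald(fit, list(con))
    v1 <- std_at(fit$estimates, waves[1])
    v2 <- std_at(fit$estimates, waves[2])
  } else {
    pre <- if (factor == "p") "lg_" else "ls_"
    l1 <- paste0(pre, indicator, "_", waves[1])
    l2 <- paste0(pre, indicator, "_", waves[2])
    if (!all(c(l1, l2) %in% names(fit$estimates))) {
      stop("loading labels not found: ", l1, ", ", l2)
    }
    test <- sem_wald(fit, list(c(l1, l2)))
    v1 <- fit$estimates[[l1]]; v2 <- fit$estimates[[l2]]
  }
  list(test = test, direction = sign(v2 - v1),
       loading_first = v1, loading_last = v2,
       standardized = standardized)
}
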