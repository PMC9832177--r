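# Random-intercept cross-lagged panel models: the four-variant comparison
# family (baseline, two unidirectional, bidirectional "mutualism"), the
# traditional CLPM obtained by fixing the random-intercept (co)variances to
# zero, and parameter extraction.

riclpm_variants <- c("baseline", "int_to_ext", "ext_to_int",
                     "bidirectional", "clpm")

#' Build a random-intercept cross-lagged panel model specification
#'
#' Two observed series (internalizing and externalizing composites per wave,
#' named `int.<age>` / `ext.<age>`). Each series has a random-intercept
#' latent with unit loadings on all its waves (stable between-person level)
#' and per-wave within-person deviation latents carrying the lag-1 dynamics.
#' Autoregressions are always free; cross-lags per variant; random-intercept
#' variances and covariance free except in the `clpm` variant, where all
#' three are fixed to 0 (the traditional cross-lagged panel model). Grand
#' means are free intercepts per wave; wave-1 deviations are exogenous with
#' free variance/covariance; within-time deviation (residual) covariances
#' are free at every wave. Observed residuals are fixed to 0 so all variance
#' flows through the decomposition.
#'
#' @param waves Integer age labels, length `>= 3`.
#' @param variant One of `"baseline"`, `"int_to_ext"`, `"ext_to_int"`,
#'   `"bidirectional"`, `"clpm"`.
#' @return A [sem_spec].
#' @export
build_riclpm_spec <- function(waves, variant = riclpm_variants) {
  variant <- match.arg(variant)
  waves <- as.integer(waves)
  W <- length(waves)
  if (W < 3) stop("the RI-CLPM needs at least 3 waves for identification")
  series <- c("int", "ext")
  obs <- paste0(rep(series, times = W), ".", rep(waves, each = 2))
  ri <- paste0("ri_", series)
  wl <- paste0(rep(paste0("w_", series), times = W), ".", rep(waves, each = 2))
  lat <- c(ri, wl)
  ko <- length(obs); kl <- length(lat)
  lam_v <- matrix(0, ko, kl, dimnames = list(obs, lat))
  lam_l <- matrix("", ko, kl, dimnames = list(obs, lat))
  for (s in series) for (w in waves) {
    ov <- paste0(s, ".", w)
    lam_v[ov, paste0("ri_", s)] <- 1
    lam_v[ov, paste0("w_", s, ".", w)] <- 1
  }
  th_v <- matrix(0, ko, ko, dimnames = list(obs, obs))   # residuals fixed 0
  th_l <- matrix("", ko, ko, dimnames = list(obs, obs))
  psi_v <- matrix(0, kl, kl, dimnames = list(lat, lat))
  psi_l <- matrix("", kl, kl, dimnames = list(lat, lat))
  if (variant != "clpm") {
    psi_l["ri_int", "ri_int"] <- "ri_var_int"
    psi_l["ri_ext", "ri_ext"] <- "ri_var_ext"
    psi_l["ri_int", "ri_ext"] <- psi_l["ri_ext", "ri_int"] <- "ri_cov"
    psi_v["ri_int", "ri_int"] <- psi_v["ri_ext", "ri_ext"] <- 1
  }
  for (w in seq_along(waves)) {
    a <- waves[w]
    wi <- paste0("w_int.", a); we <- paste0("w_ext.", a)
    psi_l[wi, wi] <- paste0("wv_int_", a)
    psi_l[we, we] <- paste0("wv_ext_", a)
    psi_l[wi, we] <- psi_l[we, wi] <- paste0("wc_", a)
    psi_v[wi, wi] <- psi_v[we, we] <- 0.5
  }
  beta_v <- matrix(0, kl, kl, dimnames = list(lat, lat))
  beta_l <- matrix("", kl, kl, dimnames = list(lat, lat))
  free_ie <- variant %in% c("int_to_ext", "bidirectional", "clpm")
  free_ei <- variant %in% c("ext_to_int", "bidirectional", "clpm")
  for (w in 2:W) {
    a <- waves[w]; b <- waves[w - 1]
    beta_l[paste0("w_int.", a), paste0("w_int.", b)] <- paste0("a_int_", a)
    beta_l[paste0("w_ext.", a), paste0("w_ext.", b)] <- paste0("a_ext_", a)
    if (free_ie) {
      beta_l[paste0("w_ext.", a), paste0("w_int.", b)] <- paste0("c_ie_", a)
    }
    if (free_ei) {
      beta_l[paste0("w_int.", a), paste0("w_ext.", b)] <- paste0("c_ei_", a)
    }
  }
  nu_l <- paste0("mu_", rep(series, times = W), "_", rep(waves, each = 2))
  spec <- sem_spec(obs, lat,
                   lambda = list(value = lam_v, label = lam_l),
                   beta = list(value = beta_v, label = beta_l),
                   psi = list(value = psi_v, label = psi_l),
                   theta = list(value = th_v, label = th_l),
                   nu = list(value = rep(0, ko), label = nu_l))
  attr(spec, "riclpm") <- list(waves = waves, variant = variant)
  spec
}

#' Fit and compare the RI-CLPM family
#'
#' Fits the baseline (no cross-lags), both unidirectional variants, and the
#' bidirectional ("mutualism") RI-CLPM; reports a model-comparison table
#' (chi-square, df, CFI, TLI, RMSEA, AIC), pairwise likelihood-ratio tests
#' along the nesting lattice, the AIC-best variant, and the chi-bar-square
#' boundary test of the CLPM (random-intercept variances and covariance
#' fixed to 0) against the bidirectional model.
#'
#' @param data Matrix/data frame with columns `int.<age>` / `ext.<age>`, or
#'   a two-variable [panel_data] with variables `int`, `ext`.
#' @param waves Age labels (default: inferred from the data columns).
#' @param missing Passed to [sem_fit].
#' @param chibar_method,chibar_weights,chibar_nsim,chibar_seed Controls for
#'   [sem_boundary_lrt]; the default mixture weights `(0, 0, 1/2, 1/2)` over
#'   chi-square df 0-3 are the customary approximation for two boundary
#'   variances plus their covariance.
#' @param se Compute standard errors for the winning model (default `TRUE`).
#' @return List of class `riclpm_comparison`: `table`, `fits`, `lrts`,
#'   `best` (variant name), `boundary_test`.
#' @export
compare_riclpm_family <- function(data, waves = NULL, missing = "fiml",
                                  chibar_method = "mixture",
                                  chibar_weights = c(0, 0, 0.5, 0.5),
                                  chibar_nsim = 200, chibar_seed = 1,
                                  se = TRUE) {
  if (inherits(data, "panel_data")) {
    stopifnot(all(c("int", "ext") %in% data$variables))
    waves <- waves %||% data$waves
    data <- panel_wide_matrix(data)
  }
  data <- as.matrix(data)
  if (is.null(waves)) {
    waves <- sort(unique(as.integer(sub("^.*\\.", "", colnames(data)))))
  }
  variants <- c("baseline", "int_to_ext", "ext_to_int", "bidirectional")
  fits <- list()
  for (v in variants) {
    spec <- build_riclpm_spec(waves, v)
    fits[[v]] <- tryCatch(
      sem_fit(spec, data, missing = missing,
              se = se && v == "bidirectional"),
      error = function(e) structure(list(converged = FALSE, error = conditionMessage(e)),
                                    class = "sem_fit_failure"))
  }
  conv <- vapply(fits, function(f) inherits(f, "sem_fit") && f$converged,
                 logical(1))
  tab <- do.call(rbind, lapply(variants, function(v) {
    f <- fits[[v]]
    if (inherits(f, "sem_fit") && !is.null(f$indices)) {
      data.frame(model = v, converged = conv[[v]],
                 chisq = f$indices$chisq, df = f$indices$df,
                 cfi = f$indices$cfi, tli = f$indices$tli,
                 rmsea = f$indices$rmsea, aic = f$indices$aic,
                 loglik = f$loglik, n_params = f$n_params,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model = v, converged = FALSE, chisq = NA, df = NA,
                 cfi = NA, tli = NA, rmsea = NA, aic = NA, loglik = NA,
                 n_params = NA, stringsAsFactors = FALSE)
    }
  }))
  nest_pairs <- list(c("baseline", "int_to_ext"), c("baseline", "ext_to_int"),
                     c("baseline", "bidirectional"),
                     c("int_to_ext", "bidirectional"),
                     c("ext_to_int", "bidirectional"))
  lrts <- list()
  for (pr in nest_pairs) {
    if (conv[[pr[1]]] && conv[[pr[2]]]) {
      lrts[[paste(pr, collapse = "_vs_")]] <-
        sem_lrt(fits[[pr[1]]], fits[[pr[2]]])
    }
  }
  best <- if (any(conv)) tab$model[conv][which.min(tab$aic[conv])] else NA
  boundary <- NULL
  if (conv[["bidirectional"]]) {
    clpm_fit <- tryCatch(
      sem_fit(build_riclpm_spec(waves, "clpm"), data, missing = missing,
              se = FALSE),
      error = function(e) NULL)
    if (!is.null(clpm_fit) && clpm_fit$converged) {
      boundary <- sem_boundary_lrt(clpm_fit, fits$bidirectional,
                                   method = chibar_method,
                                   weights = chibar_weights,
                                   nsim = chibar_nsim, seed = chibar_seed)
      fits$clpm <- clpm_fit
    }
  }
  structure(list(table = tab, fits = fits, lrts = lrts, best = best,
                 boundary_test = boundary, waves = waves),
            class = "riclpm_comparison")
}

#' @export
print.riclpm_comparison <- function(x, ...) {
  cat("<riclpm_comparison> best by AIC:", x$best, "\n")
  print(x$table, digits = 4, row.names = FALSE)
  if (!is.null(x$boundary_test)) {
    cat("CLPM vs bidirectional boundary test: ")
    print(x$boundary_test)
  }
  invisible(x)
}

#' Extract RI-CLPM parameter estimates
#'
#' Returns the table-shaped record of a fitted RI-CLPM: random-intercept
#' variances and correlation, per-transition autoregressions and cross-lags
#' (raw and standardized), and per-wave within-time residual correlations of
#' the deviation latents.
#'
#' @param fit A converged `sem_fit` from [build_riclpm_spec()].
#' @return List of class `riclpm_estimates`: `ri` (variances, covariance,
#'   correlation with SEs/p when available), `paths` (data frame per
#'   transition), `within_time_cor` (named per wave).
#' @export
extract_riclpm_estimates <- function(fit) {
  meta <- attr(fit$spec, "riclpm")
  if (is.null(meta)) stop("fit is not an RI-CLPM")
  if (!fit$converged) stop("fit did not converge")
  est <- fit$estimates
  waves <- meta$waves
  has_ri <- meta$variant != "clpm"
  getp <- function(l) {
    if (!l %in% names(est)) return(c(NA, NA, NA))
    e <- est[[l]]
    if (!is.null(fit$se) && l %in% names(fit$se)) {
      s <- fit$se[[l]]
      c(e, s, 2 * stats::pnorm(-abs(e / s)))
    } else c(e, NA, NA)
  }
  ri <- if (has_ri) {
    vi <- getp("ri_var_int"); ve <- getp("ri_var_ext"); cv <- getp("ri_cov")
    r <- cv[1] / sqrt(max(vi[1], 1e-300) * max(ve[1], 1e-300))
    list(var_int = vi[1], var_int_se = vi[2], var_int_p = vi[3],
         var_ext = ve[1], var_ext_se = ve[2], var_ext_p = ve[3],
         cov = cv[1], cov_se = cv[2], cov_p = cv[3], correlation = r)
  } else {
    list(var_int = 0, var_ext = 0, cov = 0, correlation = NA_real_)
  }
  std_beta <- fit$std$beta
  rows <- list()
  for (w in waves[-1]) {
    lab <- function(pre) paste0(pre, "_", w)
    prev <- waves[match(w, waves) - 1]
    g <- function(pre, from, to) {
      p <- getp(lab(pre))
      c(est = p[1], se = p[2], p = p[3],
        beta = std_beta[paste0("w_", to, ".", w), paste0("w_", from, ".", prev)])
    }
    rows[[as.character(w)]] <- data.frame(
      wave = w,
      path = c("int_to_int", "ext_to_ext", "int_to_ext", "ext_to_int"),
      rbind(g("a_int", "int", "int"), g("a_ext", "ext", "ext"),
            g("c_ie", "int", "ext"), g("c_ei", "ext", "int")),
      stringsAsFactors = FALSE)
  }
  paths <- do.call(rbind, rows)
  rownames(paths) <- NULL
  wt <- vapply(waves, function(w) {
    cv <- est[[paste0("wc_", w)]]
    vi <- est[[paste0("wv_int_", w)]]
    ve <- est[[paste0("wv_ext_", w)]]
    cv / sqrt(max(vi, 1e-300) * max(ve, 1e-300))
  }, 0)
  names(wt) <- paste0("age", waves)
  structure(list(ri = ri, paths = paths, within_time_cor = wt,
                 variant = meta$variant),
            class = "riclpm_estimates")
}

#' @export
print.riclpm_estimates <- function(x, ...) {
  cat(sprintf("<riclpm_estimates:%s> RI variances: %.3f / %.3f, r = %.3f\n",
              x$variant, x$ri$var_int, x$ri$var_ext,
              x$ri$correlation %||% NA))
  print(x$paths, digits = 3, row.names = FALSE)
  invisible(x)
}
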