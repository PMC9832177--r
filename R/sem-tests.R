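# Hypothesis tests on fitted covariance-structure models: likelihood-ratio
# tests for nested models, Wald tests of (in)equality constraints, and
# chi-bar-square tests for variance parameters restricted to the zero
# boundary.

new_sem_test <- function(kind, statistic, df, p, extra = list()) {
  structure(c(list(kind = kind, statistic = statistic, df = df, p = p), extra),
            class = "sem_test")
}

#' @export
print.sem_test <- function(x, ...) {
  dftxt <- if (length(x$df) == 1) sprintf("df = %s", format(x$df)) else
    sprintf("mixture weights = (%s)", paste(round(x$weights, 3), collapse = ", "))
  cat(sprintf("<sem_test:%s> statistic = %.4f, %s, p = %.4g\n",
              x$kind, x$statistic, dftxt, x$p))
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' @param fit_restricted,fit_full Nested `sem_fit` objects on the same data
#'   with the same missing-data mode.
#' @param tol Tolerance for a negative statistic before it is treated as an
#'   optimizer failure.
#' @return A `sem_test` with the chi-square statistic, df and p-value.
#' @export
sem_lrt <- function(fit_restricted, fit_full, tol = 1e-4) {
  if (fit_restricted$n_used != fit_full$n_used ||
      fit_restricted$missing != fit_full$missing) {
    stop("models must be fitted to the same data with the same missing mode")
  }
  stat <- 2 * (fit_full$loglik - fit_restricted$loglik)
  if (stat < -tol * (1 + abs(fit_full$loglik))) {
    stop(sprintf(
      "restricted model fits better than full (LR = %.6f): optimizer failure",
      stat))
  }
  stat <- max(stat, 0)
  df <- fit_full$n_params - fit_restricted$n_params
  if (df < 0) stop("restricted model has more parameters than the full model")
  p <- if (df == 0) as.numeric(stat <= tol) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  if (df == 0 && stat <= tol) p <- 1
  new_sem_test("lrt", stat, df, p)
}

#' Wald test of parameter constraints
#'
#' Tests `h(theta) = 0` with `W = h' (J V J')^{-1} h`, where `V` is the
#' parameter covariance matrix and `J` the constraint Jacobian (central
#' differences). Constraints are given either as label pairs (equality
#' `theta[a] - theta[b] = 0`), single labels (`theta[a] = 0`), or functions
#' of the named parameter vector.
#'
#' @param fit A converged `sem_fit` with standard errors.
#' @param constraints List; each element a character vector of length 1 or 2,
#'   or a function returning a numeric scalar/vector.
#' @return A `sem_test`.
#' @export
sem_wald <- function(fit, constraints) {
  V <- vcov(fit)
  est <- fit$estimates
  hfun <- function(theta) {
    unlist(lapply(constraints, function(con) {
      if (is.function(con)) con(theta)
      else if (length(con) == 2) theta[[con[1]]] - theta[[con[2]]]
      else theta[[con[1]]]
    }))
  }
  h <- hfun(est)
  q <- length(h)
  J <- matrix(0, q, length(est))
  for (j in seq_along(est)) {
    step <- 1e-5 * max(1, abs(est[j]))
    e1 <- est; e1[j] <- e1[j] + step
    e2 <- est; e2[j] <- e2[j] - step
    J[, j] <- (hfun(e1) - hfun(e2)) / (2 * step)
  }
  if (qr(J)$rank < q) stop("constraint Jacobian is rank deficient")
  HVH <- J %*% V %*% t(J)
  ch <- tryCatch(chol(HVH), error = function(e) NULL)
  if (is.null(ch)) {
    # Identify the offending constraint for the error message.
    dg <- sqrt(abs(diag(HVH)))
    cr <- HVH / outer(dg, dg)
    off <- which(abs(cr - diag(q)) > 0.999, arr.ind = TRUE)
    stop("singular constraint covariance (redundant constraint ",
         if (nrow(off)) off[1, 1] else "?", ")")
  }
  W <- as.numeric(crossprod(h, chol2inv(ch) %*% h))
  new_sem_test("wald", W, q, stats::pchisq(W, q, lower.tail = FALSE))
}

#' Chi-bar-square boundary test
#'
#' Likelihood-ratio test where the restriction fixes variance parameters at
#' their zero boundary (plus any associated covariances), so the null
#' distribution is a mixture of chi-squares rather than a single chi-square.
#' `method = "mixture"` uses supplied mixture weights (default the exact
#' (1/2, 1/2) weights on chi^2_0 : chi^2_1 for a single boundary variance);
#' `method = "simulation"` estimates the null distribution by parametric
#' simulation under the restricted fit.
#'
#' @param fit_restricted,fit_full Nested fits as in [sem_lrt]; the restricted
#'   model must fix the tested variances (and covariances) to 0.
#' @param method `"mixture"` or `"simulation"`.
#' @param weights Mixture weights over chi-square df `0, 1, ..., q` for
#'   `method = "mixture"`.
#' @param nsim Parametric draws for `method = "simulation"` (default 500).
#' @param seed Seed for the simulation method.
#' @return A `sem_test` with `kind = "chibar"`; for the simulation method the
#'   result also carries the simulated statistics and estimated point mass at
#'   zero.
#' @export
sem_boundary_lrt <- function(fit_restricted, fit_full,
                             method = c("mixture", "simulation"),
                             weights = NULL, nsim = 500, seed = 1) {
  method <- match.arg(method)
  base <- sem_lrt(fit_restricted, fit_full)
  stat <- base$statistic
  q <- base$df
  if (stat <= .Machine$double.eps^0.5 && method == "mixture") {
    return(new_sem_test("chibar", stat, q, 1,
                        list(weights = weights %||% c(0.5, 0.5))))
  }
  if (method == "mixture") {
    if (is.null(weights)) weights <- c(0.5, 0.5)  # single boundary variance
    dfs <- seq_along(weights) - 1
    p <- sum(weights * vapply(dfs, function(d) {
      if (d == 0) 0 else stats::pchisq(stat, d, lower.tail = FALSE)
    }, 0))
    new_sem_test("chibar", stat, q, p, list(weights = weights))
  } else {
    imp <- fit_restricted$implied
    n <- fit_restricted$n_used
    stats_sim <- with_seed(seed, {
      vapply(seq_len(nsim), function(b) {
        xb <- rmvn(n, imp$mu, imp$sigma)
        colnames(xb) <- fit_restricted$spec$obs
        fr <- sem_fit(fit_restricted$spec, xb, missing = fit_restricted$missing,
                      se = FALSE, baseline = FALSE)
        ff <- sem_fit(fit_full$spec, xb, missing = fit_full$missing,
                      se = FALSE, baseline = FALSE,
                      start = stats::setNames(
                        fr$estimates[intersect(names(fr$estimates),
                                               names(fit_full$estimates))],
                        intersect(names(fr$estimates), names(fit_full$estimates))))
        max(0, 2 * (ff$loglik - fr$loglik))
      }, 0)
    })
    w0 <- mean(stats_sim < 1e-6)
    p <- (1 + sum(stats_sim >= stat)) / (nsim + 1)
    new_sem_test("chibar", stat, q, p,
                 list(weights = c(w0, 1 - w0), sim_stats = stats_sim,
                      nsim = nsim, seed = seed))
  }
}

# Merge label groups: every label in `group` is replaced by its first element.
relabel_spec <- function(spec, groups) {
  map <- character(0)
  for (g in groups) {
    if (length(g) > 1) map[g[-1]] <- g[1]
  }
  sub <- function(lab) {
    hit <- lab %in% names(map)
    lab[hit] <- map[lab[hit]]
    lab
  }
  for (nm in c("lambda", "beta", "psi", "theta")) {
    spec[[nm]]$label[] <- sub(spec[[nm]]$label)
  }
  spec$nu$label <- sub(spec$nu$label)
  spec$alpha$label <- sub(spec$alpha$label)
  spec
}

#' Longitudinal measurement-invariance ladder
#'
#' Fits the configural model (all wave-specific loadings and intercepts
#' free), then the metric model (loadings of each indicator-factor pair
#' constrained equal across waves), then the scalar model (intercepts also
#' equal), comparing successive steps by likelihood-ratio tests. Constraint
#' groups are read from the spec's `invariance` attribute (lists of label
#' vectors), which model builders such as [build_bifactor_spec()] attach.
#'
#' @param spec A [sem_spec] carrying an `invariance` attribute with elements
#'   `metric` and `scalar` (lists of cross-wave label groups).
#' @param data Data as in [sem_fit].
#' @param levels Which rungs to fit.
#' @param release Character vector of group names (first label of a group)
#'   exempted from constraint, for partial invariance.
#' @param ... Passed to [sem_fit].
#' @return List of per-level results: `fit` and `test` (LRT against the
#'   previous rung; `NULL` for the first).
#' @export
invariance_ladder <- function(spec, data,
                              levels = c("configural", "metric", "scalar"),
                              release = NULL, ...) {
  inv <- attr(spec, "invariance")
  if (is.null(inv)) stop("spec carries no invariance groups")
  levels <- match.arg(levels, several.ok = TRUE)
  keep <- function(groups) {
    groups[!vapply(groups, function(g) g[1] %in% release, logical(1))]
  }
  free_var <- function(s) {
    for (l in inv$metric_free_var %||% character(0)) {
      j <- match(l, s$lat)
      s$psi$label[j, j] <- paste0("fv_", l)
      s$psi$value[j, j] <- 1
    }
    s
  }
  free_mean <- function(s) {
    for (l in inv$scalar_free_mean %||% character(0)) {
      j <- match(l, s$lat)
      s$alpha$label[j] <- paste0("fm_", l)
    }
    s
  }
  specs <- list()
  if ("configural" %in% levels) specs$configural <- spec
  if ("metric" %in% levels) {
    specs$metric <- free_var(relabel_spec(spec, keep(inv$metric)))
    attr(specs$metric, "invariance") <- inv
  }
  if ("scalar" %in% levels) {
    specs$scalar <- free_mean(free_var(
      relabel_spec(spec, c(keep(inv$metric), keep(inv$scalar)))))
  }
  out <- list()
  prev <- NULL
  for (nm in names(specs)) {
    fit <- sem_fit(specs[[nm]], data, ...)
    test <- if (!is.null(prev)) sem_lrt(fit, prev) else NULL
    out[[nm]] <- list(level = nm, fit = fit, test = test)
    prev <- fit
  }
  out
}
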