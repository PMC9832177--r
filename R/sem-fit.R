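# Normal-theory ML / FIML estimation of covariance-structure models.
#
# The objective is F(theta) = -2 log L under the multivariate normal model,
# with the likelihood using the ML (n-denominator) convention. FIML sums
# pattern-wise Gaussian log-likelihoods over missingness patterns (exact,
# no imputation). Gradients are analytic; see the matrix identities inline.

# Default starting values per the package's documented rules.
default_start <- function(spec, pt, data_stats) {
  sds <- data_stats$sd; vars <- sds^2; means <- data_stats$mean
  k <- length(spec$obs)
  start <- numeric(length(pt$labels))
  names(start) <- pt$labels
  agg <- stats::setNames(vector("list", length(pt$labels)), pt$labels)
  for (r in seq_len(nrow(pt$cells))) {
    c0 <- pt$cells[r, ]
    s <- switch(
      c0$mat,
      lambda = 0.5 * sds[c0$i],
      beta = 0.1,
      psi = if (c0$i == c0$j) {
        # If the latent has a fixed unit loading, inherit half that
        # indicator's variance; otherwise start at 1.
        jj <- c0$i
        fixed1 <- which(!nzchar(spec$lambda$label[, jj]) &
                          spec$lambda$value[, jj] != 0)
        if (length(fixed1)) 0.5 * vars[fixed1[1]] else 1
      } else 0,
      theta = if (c0$i == c0$j) 0.5 * vars[c0$i] else 0,
      nu = means[c0$i],
      alpha = 0
    )
    agg[[c0$label]] <- c(agg[[c0$label]], s)
  }
  for (l in pt$labels) start[l] <- mean(agg[[l]])
  start[!is.finite(start)] <- 0.1
  start
}

#' Fit a covariance-structure model by ML or FIML
#'
#' Maximizes the multivariate-normal log-likelihood of a [sem_spec] over its
#' free parameters with a quasi-Newton optimizer (analytic gradient,
#' variances box-bounded at 0). `missing = "fiml"` uses full-information ML:
#' rows are grouped into missingness patterns and pattern-wise Gaussian
#' log-likelihoods are summed. `missing = "listwise"` keeps complete rows
#' only.
#'
#' @param spec A [sem_spec].
#' @param data Numeric matrix or data frame whose columns include
#'   `spec$obs`, or a [panel_data] (flattened via [panel_wide_matrix]).
#' @param missing `"fiml"` (default) or `"listwise"`.
#' @param se Compute standard errors from the inverse observed information
#'   (default `TRUE`; skip in simulations for speed).
#' @param start Optional named vector of starting values (label -> value).
#' @param control List: `rel_tol` (objective tolerance, default 1e-10),
#'   `max_iter` (default 2000), `grad_tol` (per-observation gradient
#'   criterion backing the convergence flag, default 1e-4; well-specified
#'   models typically reach 1e-5 or better).
#' @param baseline Also fit the independence baseline and compute CFI / TLI /
#'   RMSEA (default `TRUE`).
#' @return An object of class `sem_fit`; see [summary.sem_fit()].
#' @export
sem_fit <- function(spec, data, missing = c("fiml", "listwise"), se = TRUE,
                    start = NULL, control = list(), baseline = TRUE) {
  missing <- match.arg(missing)
  if (inherits(data, "panel_data")) data <- panel_wide_matrix(data)
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("data must have column names")
  miss_cols <- setdiff(spec$obs, colnames(data))
  if (length(miss_cols)) {
    stop("data lacks variables: ", paste(miss_cols, collapse = ", "))
  }
  x <- data[, spec$obs, drop = FALSE]
  if (missing == "listwise") x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  pats <- missing_patterns(x)
  n <- attr(pats, "n_used")
  pt <- spec_param_table(spec)
  npar <- length(pt$labels)
  moments <- k * (k + 1) / 2 + if (spec$meanstructure) k else 0
  df <- moments - npar
  if (df < 0) stop("model has negative degrees of freedom (", df, ")")
  ctrl <- utils::modifyList(
    list(rel_tol = 1e-10, max_iter = 2000L, grad_tol = 1e-4,
         grad_tol_rel = 1e-5), control)

  data_stats <- list(
    mean = vapply(seq_len(k), function(j) mean(x[, j], na.rm = TRUE), 0),
    sd = vapply(seq_len(k), function(j) stats::sd(x[, j], na.rm = TRUE), 0))
  th0 <- default_start(spec, pt, data_stats)
  if (!is.null(start)) th0[names(start)[names(start) %in% names(th0)]] <-
      start[names(start) %in% names(th0)]
  lower <- pt$lower

  # Precomputed cell bookkeeping for the vectorized gradient.
  cells <- pt$cells
  gp <- list(
    li = match(cells$label, pt$labels),
    mat = cells$mat, ij = cbind(cells$i, cells$j), i = cells$i,
    mult = ifelse(cells$mat %in% c("psi", "theta") & cells$i != cells$j, 2, 1))

  cache <- new.env(parent = emptyenv())
  eval_point <- function(theta_vec) {
    if (!is.null(cache$theta) && length(cache$theta) == length(theta_vec) &&
          all(cache$theta == theta_vec)) {
      return(cache$val)
    }
    key_theta <- theta_vec
    names(theta_vec) <- pt$labels
    mats <- spec_matrices(spec, theta_vec)
    imp <- implied_moments(mats)
    # F, Omega = dF/dSigma (full, symmetric), g_mu = dF/dmu
    Fv <- 0
    Om <- matrix(0, k, k)
    gmu <- numeric(k)
    ok <- TRUE
    for (p in pats) {
      o <- p$idx
      so <- imp$sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(so), error = function(e) NULL)
      if (is.null(ch)) { ok <- FALSE; break }
      si <- chol2inv(ch)
      d <- p$mean - imp$mu[o]
      A <- p$cov + tcrossprod(d)
      Fv <- Fv + p$n * (length(o) * log(2 * pi) +
                          2 * sum(log(diag(ch))) + sum(si * A))
      Om[o, o] <- Om[o, o] + p$n * (si - si %*% A %*% si)
      gmu[o] <- gmu[o] - 2 * p$n * as.vector(si %*% d)
    }
    val <- if (!ok) list(F = 1e14, bad = TRUE) else {
      list(F = Fv, bad = FALSE, mats = mats, imp = imp, Om = Om, gmu = gmu)
    }
    cache$theta <- key_theta; cache$val <- val
    val
  }
  objective <- function(theta_vec) eval_point(theta_vec)$F
  gradient <- function(theta_vec) {
    ev <- eval_point(theta_vec)
    if (ev$bad) return(numeric(length(theta_vec)))
    imp <- ev$imp; Om <- ev$Om; gmu <- ev$gmu
    Malpha <- as.vector(imp$M %*% ev$mats$alpha)
    LamE <- ev$mats$lambda %*% imp$E
    GL <- 2 * Om %*% LamE + outer(gmu, Malpha)
    Gg <- as.vector(crossprod(imp$G, gmu))         # G' g_mu
    OmLam <- Om %*% ev$mats$lambda
    GB <- 2 * t(imp$M) %*% crossprod(ev$mats$lambda, OmLam %*% imp$E) +
      outer(Gg, Malpha)
    CP <- crossprod(imp$G, Om) %*% imp$G           # G' Om G
    contrib <- numeric(length(gp$li))
    sel <- gp$mat == "lambda"
    if (any(sel)) contrib[sel] <- GL[gp$ij[sel, , drop = FALSE]]
    sel <- gp$mat == "beta"
    if (any(sel)) contrib[sel] <- GB[gp$ij[sel, , drop = FALSE]]
    sel <- gp$mat == "psi"
    if (any(sel)) contrib[sel] <- gp$mult[sel] * CP[gp$ij[sel, , drop = FALSE]]
    sel <- gp$mat == "theta"
    if (any(sel)) contrib[sel] <- gp$mult[sel] * Om[gp$ij[sel, , drop = FALSE]]
    sel <- gp$mat == "nu"
    if (any(sel)) contrib[sel] <- gmu[gp$i[sel]]
    sel <- gp$mat == "alpha"
    if (any(sel)) contrib[sel] <- Gg[gp$i[sel]]
    g <- numeric(length(theta_vec))
    tab <- rowsum(contrib, gp$li)
    g[as.integer(rownames(tab))] <- tab[, 1]
    g
  }

  opt <- stats::nlminb(th0, objective, gradient, lower = lower,
                       control = list(iter.max = ctrl$max_iter,
                                      eval.max = 4 * ctrl$max_iter,
                                      rel.tol = ctrl$rel_tol))
  # Restart (fresh quasi-Newton Hessian) while the gradient criterion is
  # unmet and restarts still improve the objective. A restart that no
  # longer improves the objective marks the point as stationary even when
  # extreme curvature keeps the raw gradient large.
  stationary <- FALSE
  for (tries in 1:5) {
    gr0 <- gradient(opt$par)
    ab0 <- lower > -Inf & opt$par <= lower + 1e-10 & gr0 > 0
    if (all(ab0) || max(abs(gr0[!ab0])) / (2 * n) < ctrl$grad_tol) break
    opt2 <- stats::nlminb(opt$par, objective, gradient, lower = lower,
                          control = list(iter.max = ctrl$max_iter,
                                         rel.tol = ctrl$rel_tol))
    if (opt2$objective > opt$objective - 1e-6 * (1 + abs(opt$objective))) {
      stationary <- TRUE
      if (opt2$objective < opt$objective) opt <- opt2
      break
    }
    opt <- opt2
  }
  gr_ok <- function(o) {
    g <- gradient(o$par)
    ab <- lower > -Inf & o$par <= lower + 1e-10 & g > 0
    all(ab) || max(abs(g[!ab])) / (2 * n) < ctrl$grad_tol
  }
  if (opt$convergence != 0 && !gr_ok(opt)) {
    # Deterministic fallback start: high-communality profile (helps when
    # residual variances are near their boundary).
    th_alt <- th0
    for (r in seq_len(nrow(cells))) {
      if (cells$mat[r] == "lambda") {
        th_alt[cells$label[r]] <- 0.9 * data_stats$sd[cells$i[r]]
      } else if (cells$mat[r] == "theta" && cells$i[r] == cells$j[r]) {
        th_alt[cells$label[r]] <- 0.1 * data_stats$sd[cells$i[r]]^2
      }
    }
    opt_alt <- stats::nlminb(th_alt, objective, gradient, lower = lower,
                             control = list(iter.max = ctrl$max_iter,
                                            eval.max = 4 * ctrl$max_iter,
                                            rel.tol = ctrl$rel_tol))
    if (opt_alt$objective < opt$objective) {
      opt <- opt_alt
      polish <- stats::nlminb(opt$par, objective, gradient, lower = lower,
                              control = list(iter.max = ctrl$max_iter,
                                             rel.tol = ctrl$rel_tol))
      if (polish$objective > opt$objective - 1e-6 * (1 + abs(opt$objective))) {
        stationary <- TRUE
      }
      if (polish$objective < opt$objective) opt <- polish
    }
  }
  est <- opt$par
  names(est) <- pt$labels
  gr <- gradient(est)
  # Gradient diagnostics, ignoring components pinned at a bound: the
  # per-observation max component (reported) and a scaled relative gradient
  # (backs the convergence flag; robust to boundary curvature scales).
  at_bound <- lower > -Inf & est <= lower + 1e-10 & gr > 0
  free_gr <- abs(gr[!at_bound])
  grad_norm <- if (all(at_bound)) 0 else max(free_gr) / (2 * n)
  rel_grad <- if (all(at_bound)) 0 else
    max(free_gr * pmax(abs(est[!at_bound]), 1e-3)) / (1 + abs(opt$objective))
  converged <- opt$convergence == 0 || rel_grad < ctrl$grad_tol_rel ||
    stationary
  mats <- spec_matrices(spec, est)
  imp <- implied_moments(mats)

  warn <- character(0)
  psi_ev <- eigen((imp$E + t(imp$E)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
  if (min(psi_ev) < -1e-8) warn <- c(warn, "latent covariance not PSD")
  th_ev <- eigen(mats$theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(th_ev) < -1e-8) warn <- c(warn, "residual covariance not PSD")

  loglik <- -opt$objective / 2
  fit <- structure(list(
    spec = spec, estimates = est, se = NULL, vcov = NULL,
    loglik = loglik, n_params = npar, df = df, n_used = n,
    missing = missing, converged = converged, grad_norm = grad_norm,
    rel_grad = rel_grad,
    matrices = mats, implied = list(mu = imp$mu, sigma = imp$sigma),
    latent_cov = imp$E, patterns = pats, data = x,
    warnings = warn, optimizer = list(convergence = opt$convergence,
                                      message = opt$message,
                                      iterations = opt$iterations)
  ), class = "sem_fit")
  fit$std <- standardize_fit(fit)

  if (se) {
    H <- grad_hessian(gradient, est, lower)
    fit$vcov <- tryCatch({
      V <- 2 * solve((H + t(H)) / 2)
      dimnames(V) <- list(pt$labels, pt$labels)
      V
    }, error = function(e) NULL)
    if (is.null(fit$vcov)) {
      fit$warnings <- c(fit$warnings, "information matrix singular; no SEs")
    } else {
      dv <- diag(fit$vcov)
      fit$se <- stats::setNames(sqrt(pmax(dv, 0)), pt$labels)
      if (any(dv < 0)) {
        fit$warnings <- c(fit$warnings, "negative variance in inverse information")
      }
    }
  }
  if (baseline) fit <- fit_indices(fit)
  fit
}

# Central-difference Hessian of F from the analytic gradient. Steps shrink
# near active lower bounds to stay in the feasible region.
grad_hessian <- function(gradient, est, lower) {
  p <- length(est)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(est[j]))
    lo <- if (is.finite(lower[j])) est[j] - lower[j] else Inf
    if (lo < h) h <- max(lo / 2, 1e-10)
    e1 <- est; e1[j] <- e1[j] + h
    e2 <- est; e2[j] <- e2[j] - h
    H[, j] <- (gradient(e1) - gradient(e2)) / (2 * h)
  }
  H
}

# Completely standardized solution computed from model-implied variances.
standardize_fit <- function(fit) {
  mats <- fit$matrices
  sdo <- sqrt(diag(fit$implied$sigma))
  sdl <- sqrt(pmax(diag(fit$latent_cov), 0))
  lambda_std <- sweep(sweep(mats$lambda, 2L, sdl, `*`), 1L, sdo, `/`)
  beta_std <- mats$beta * outer(1 / pmax(sdl, 1e-300), sdl)
  lat_cor <- fit$latent_cov / outer(pmax(sdl, 1e-300), pmax(sdl, 1e-300))
  theta_std <- mats$theta / outer(sdo, sdo)
  list(lambda = lambda_std, beta = beta_std, latent_cor = lat_cor,
       theta = theta_std)
}

#' Compute chi-square based fit indices for a fitted model
#'
#' Anchors the model chi-square at the saturated log-likelihood (closed form
#' on complete data; EM-estimated Gaussian moments under missingness) and
#' computes CFI, TLI, RMSEA (with 90% CI) and AIC against the independence
#' (diagonal-covariance) baseline. Adequacy uses the conventional cutoffs
#' CFI/TLI >= .90 and RMSEA <= .06.
#'
#' @param fit A `sem_fit` object.
#' @param baseline Optional independence-model `sem_fit` on the same data;
#'   computed in closed form when omitted.
#' @return The fit with a populated `$indices` list.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  pats <- fit$patterns
  n <- fit$n_used
  k <- length(fit$spec$obs)
  complete <- length(pats) == 1 && length(pats[[1]]$idx) == k
  if (complete) {
    p <- pats[[1]]
    ll_sat <- -0.5 * fiml_m2ll(pats, p$mean, p$cov)
  } else {
    em <- em_covariance(fit$data)
    ll_sat <- em$loglik
  }
  if (is.null(baseline)) {
    ll_b <- 0
    for (j in seq_len(k)) {
      xj <- fit$data[, j]
      xj <- xj[!is.na(xj)]
      v <- mean((xj - mean(xj))^2)
      ll_b <- ll_b - 0.5 * length(xj) * (log(2 * pi) + log(v) + 1)
    }
    npar_b <- 2 * k
  } else {
    ll_b <- baseline$loglik
    npar_b <- baseline$n_params
  }
  moments <- k * (k + 1) / 2 + if (fit$spec$meanstructure) k else 0
  chisq <- max(0, 2 * (ll_sat - fit$loglik))
  df <- fit$df
  chisq_b <- max(0, 2 * (ll_sat - ll_b))
  df_b <- moments - npar_b
  num_m <- max(chisq - df, 0)
  num_b <- max(chisq_b - df_b, 0)
  cfi <- if (max(num_m, num_b) == 0) 1 else 1 - num_m / max(num_b, num_m)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b != 1) {
    (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1)
  } else NA_real_
  tli_reported <- if (!is.na(tli)) min(tli, 1) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * n)) else NA_real_
  rmsea_ci <- if (df > 0) rmsea_interval(chisq, df, n) else c(NA_real_, NA_real_)
  p_chisq <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  adequate <- !is.na(cfi) && !is.na(rmsea) &&
    cfi >= .90 && (!is.na(tli_reported) && tli_reported >= .90) && rmsea <= .06
  fit$indices <- list(
    chisq = chisq, df = df, p = p_chisq,
    chisq_baseline = chisq_b, df_baseline = df_b,
    cfi = cfi, tli = tli_reported, tli_raw = tli,
    rmsea = rmsea, rmsea_ci90 = rmsea_ci,
    aic = -2 * fit$loglik + 2 * fit$n_params,
    loglik_saturated = ll_sat, loglik_baseline = ll_b,
    adequate = adequate,
    rmsea_defined = df > 0
  )
  fit
}

# Standard noncentrality-based 90% RMSEA interval.
rmsea_interval <- function(chisq, df, n) {
  f <- function(ncp, q) stats::pchisq(chisq, df, ncp = ncp) - q
  upper_limit <- max(chisq * 2, df * 10, 100)
  lo <- if (f(0, 0.95) < 0) 0 else
    stats::uniroot(f, c(0, upper_limit), q = 0.95, extendInt = "downX")$root
  hi <- if (f(0, 0.05) < 0) 0 else
    stats::uniroot(f, c(0, upper_limit), q = 0.05, extendInt = "downX")$root
  sqrt(pmax(c(lo, hi), 0) / (df * n))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %d free parameters, df = %d, n = %d (%s)\n",
              x$n_params, x$df, x$n_used, x$missing))
  cat(sprintf("  logLik = %.3f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$indices)) {
    cat(sprintf("  chisq(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, AIC = %.1f\n",
                x$indices$df, x$indices$chisq, x$indices$cfi, x$indices$tli,
                x$indices$rmsea, x$indices$aic))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(label = names(est), estimate = unname(est),
                    stringsAsFactors = FALSE)
  if (!is.null(object$se)) {
    tab$se <- unname(object$se[tab$label])
    tab$z <- tab$estimate / tab$se
    tab$p <- 2 * stats::pnorm(-abs(tab$z))
  }
  structure(list(table = tab, fit = object), class = "summary.sem_fit")
}

#' @export
print.summary.sem_fit <- function(x, ...) {
  print(x$fit)
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) object$estimates

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_used,
            class = "logLik")
}

#' @export
vcov.sem_fit <- function(object, ...) {
  if (is.null(object$vcov)) stop("fit was run with se = FALSE")
  object$vcov
}

#' @export
AIC.sem_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$n_params
}

#' Export a fitted model's parameter table to CSV / JSON
#'
#' @param fit A `sem_fit`.
#' @param csv_path,json_path Optional output paths.
#' @return The parameter table data frame, invisibly.
#' @export
sem_fit_export <- function(fit, csv_path = NULL, json_path = NULL) {
  tab <- summary(fit)$table
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(parameters = tab, loglik = fit$loglik, n = fit$n_used,
           indices = fit$indices),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(tab)
}
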