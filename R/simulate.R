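# Synthetic longitudinal symptom panels under three competing
# data-generating processes:
#   common_cause   - orthogonal AR(1) latent factors (p, INT, EXT) with a
#                    bifactor measurement structure,
#   mutualism      - a lag-1 VAR among observed composites whose cross-domain
#                    couplings strengthen linearly across transitions,
#   differentiation- the same VAR with weakening couplings.
# Every generator is fully seeded and emits its ground truth alongside the
# panel so downstream checks are recovery tests.

default_variables <- c("gad", "mdd", "adhd", "cdaspd", "odd", "subuse")
default_domains <- c(gad = "int", mdd = "int", adhd = "ext", cdaspd = "ext",
                     odd = "ext", subuse = "ext")

#' Configure a synthetic data-generating process
#'
#' Defaults emulate the reference panel design: ~2,300 subjects, 8 annual
#' waves (ages 14-21), six composite measures (two internalizing, four
#' externalizing), moderate positive cross-domain correlations, wave-on-wave
#' autocorrelation, and monotone attrition of about 13% per transition.
#' Loadings and couplings not fixed by the study design are calibration
#' choices documented in the methods vignette.
#'
#' @param dgp_kind `"common_cause"`, `"mutualism"` or `"differentiation"`.
#' @param n_subjects Number of subjects (default 2300).
#' @param n_waves Number of waves (default 8).
#' @param first_age Age label of the first wave (default 14).
#' @param variable_names Measure names (default the six composites).
#' @param domains Named map variable -> `"int"`/`"ext"`.
#' @param general_loadings,specific_loadings Per-variable loadings on the
#'   general and domain factor (common-cause kind). Residual variances are
#'   set to `1 - lg^2 - ls^2` so indicators have unit variance.
#' @param factor_ar AR(1) coefficients for the p, INT and EXT factors
#'   (stationary, unit marginal variance).
#' @param coupling_start,coupling_end Total cross-domain VAR coupling at the
#'   first and last transition (mutualism/differentiation kinds); the value
#'   is split evenly across source variables of the other domain. Defaults
#'   depend on the kind: mutualism ramps 0 -> 0.3, differentiation 0.3 -> 0
#'   (the endpoint magnitude is of the order of the late-adolescence
#'   cross-lagged coefficients reported for such panels).
#' @param within_ar VAR diagonal (per-variable carry-over).
#' @param within_domain_coupling Total same-domain off-diagonal coupling,
#'   split evenly across same-domain sources.
#' @param innovation_cov Innovation covariance of the VAR (default identity).
#' @param baseline_cor Wave-1 correlations for the VAR kinds, named vector
#'   `c(within = , cross = )` (default 0.30 within domain, 0.15 across):
#'   subjects enter the panel with a modest positive manifold already in
#'   place.
#' @param means Per-variable intercepts (default 0).
#' @param attrition_hazard Per-transition dropout hazard, scalar or length
#'   `n_waves - 1` (default 0.13).
#' @param mar_on Optional variable name driving missingness-at-random
#'   attrition (see [apply_attrition]).
#' @param likert Optional threshold vector passed to [discretize_to_likert].
#' @param seed Mandatory integer seed.
#' @return An object of class `dgp_config`.
#' @export
dgp_config <- function(dgp_kind = c("common_cause", "mutualism", "differentiation"),
                       n_subjects = 2300, n_waves = 8, first_age = 14,
                       variable_names = default_variables,
                       domains = default_domains[variable_names],
                       general_loadings = NULL, specific_loadings = NULL,
                       factor_ar = c(p = 0.75, int = 0.55, ext = 0.60),
                       coupling_start = NULL, coupling_end = NULL,
                       within_ar = 0.5, within_domain_coupling = 0.1,
                       innovation_cov = NULL,
                       baseline_cor = c(within = 0.30, cross = 0.15),
                       means = NULL,
                       attrition_hazard = 0.13, mar_on = NULL,
                       likert = NULL, seed) {
  dgp_kind <- match.arg(dgp_kind)
  if (missing(seed)) stop("a seed is mandatory")
  k <- length(variable_names)
  stopifnot(n_waves >= 2, n_subjects >= 2, k >= 2)
  domains <- domains[variable_names]
  if (any(is.na(domains)) || !all(domains %in% c("int", "ext"))) {
    stop("every variable needs a domain assignment ('int' or 'ext')")
  }
  # Heterogeneous loadings keep the general/specific decomposition
  # well-conditioned (near-proportional general and specific loading
  # vectors make the bifactor split empirically under-identified).
  general_loadings <- general_loadings %||%
    stats::setNames(c(0.50, 0.65, 0.65, 0.55, 0.60, 0.40), default_variables)[
      variable_names]
  if (any(is.na(general_loadings))) {
    general_loadings <- rep_len(0.6, k)
    names(general_loadings) <- variable_names
  }
  specific_loadings <- specific_loadings %||%
    stats::setNames(c(0.55, 0.40, 0.30, 0.50, 0.40, 0.55), default_variables)[
      variable_names]
  if (any(is.na(specific_loadings))) {
    specific_loadings <- stats::setNames(
      ifelse(domains == "int", 0.50, 0.40), variable_names)
  }
  resid <- 1 - general_loadings^2 - specific_loadings^2
  if (dgp_kind == "common_cause" && any(resid <= 0)) {
    stop("loadings imply non-positive residual variances")
  }
  if (is.null(names(factor_ar))) names(factor_ar) <- c("p", "int", "ext")
  if (is.null(names(baseline_cor))) {
    names(baseline_cor) <- c("within", "cross")[seq_along(baseline_cor)]
  }
  stopifnot(all(c("p", "int", "ext") %in% names(factor_ar)),
            all(c("within", "cross") %in% names(baseline_cor)))
  if (any(abs(factor_ar) >= 1)) stop("|factor_ar| must be < 1")
  coupling_start <- coupling_start %||%
    (if (dgp_kind == "differentiation") 0.3 else 0)
  coupling_end <- coupling_end %||%
    (if (dgp_kind == "differentiation") 0 else 0.3)
  if (dgp_kind == "mutualism" && coupling_end < coupling_start) {
    stop("mutualism requires coupling_end >= coupling_start")
  }
  if (dgp_kind == "differentiation" && coupling_end > coupling_start) {
    stop("differentiation requires coupling_end <= coupling_start")
  }
  if (is.null(innovation_cov)) {
    # Correlated innovations (unit variances): shocks to symptom domains
    # co-occur within a year, which keeps contemporaneous cross-domain
    # correlations at the moderate positive levels the panel emulates.
    innovation_cov <- matrix(0.10, k, k)
    for (d in c("int", "ext")) {
      idx <- which(domains == d)
      innovation_cov[idx, idx] <- 0.25
    }
    diag(innovation_cov) <- 1
  }
  if (!is_symmetric(innovation_cov) ||
      min(eigen(innovation_cov, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("innovation_cov must be symmetric positive definite")
  }
  attrition_hazard <- rep_len(attrition_hazard, n_waves - 1)
  if (any(attrition_hazard < 0 | attrition_hazard > 1)) {
    stop("attrition hazards must lie in [0, 1]")
  }
  means <- means %||% stats::setNames(rep(0, k), variable_names)
  if (length(mar_on) != 1 || is.na(mar_on)) mar_on <- NULL
  else mar_on <- as.character(mar_on)
  if (length(likert) == 0) likert <- NULL
  cfg <- structure(list(
    dgp_kind = dgp_kind, n_subjects = n_subjects, n_waves = n_waves,
    first_age = first_age, variable_names = variable_names, domains = domains,
    general_loadings = general_loadings, specific_loadings = specific_loadings,
    residual_var = resid, factor_ar = factor_ar,
    coupling_start = coupling_start, coupling_end = coupling_end,
    within_ar = within_ar, within_domain_coupling = within_domain_coupling,
    innovation_cov = innovation_cov, baseline_cor = baseline_cor,
    means = means,
    attrition_hazard = attrition_hazard, mar_on = mar_on,
    likert = likert, seed = as.integer(seed)
  ), class = "dgp_config")
  if (dgp_kind != "common_cause") {
    # Validate stationarity of every transition matrix up front.
    for (A in var_coefficients(cfg)) {
      if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
        stop("explosive VAR: spectral radius of a transition matrix >= 1")
      }
    }
  }
  cfg
}

#' @export
print.dgp_config <- function(x, ...) {
  cat(sprintf("<dgp_config:%s> %d subjects x %d waves x %d variables, seed %d\n",
              x$dgp_kind, x$n_subjects, x$n_waves,
              length(x$variable_names), x$seed))
  invisible(x)
}

# Lag-1 VAR coefficient matrices for every transition; cross-domain entries
# interpolate linearly from coupling_start to coupling_end.
var_coefficients <- function(config) {
  k <- length(config$variable_names)
  W <- config$n_waves
  dom <- config$domains
  n_int <- sum(dom == "int"); n_ext <- sum(dom == "ext")
  couplings <- if (W == 2) config$coupling_end else
    seq(config$coupling_start, config$coupling_end, length.out = W - 1)
  lapply(seq_len(W - 1), function(t) {
    A <- diag(config$within_ar, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (dom[i] == dom[j]) {
        nsrc <- if (dom[j] == "int") n_int else n_ext
        if (nsrc > 1) A[i, j] <- config$within_domain_coupling / (nsrc - 1)
      } else {
        nsrc <- if (dom[j] == "int") n_int else n_ext
        A[i, j] <- couplings[t] / nsrc
      }
    }
    dimnames(A) <- list(config$variable_names, config$variable_names)
    A
  })
}

# Implied wave-1 covariance of the common-cause measurement model.
common_cause_implied_cov <- function(config) {
  lg <- config$general_loadings; ls <- config$specific_loadings
  dom <- config$domains
  k <- length(lg)
  sig <- outer(lg, lg)
  for (d in c("int", "ext")) {
    idx <- which(dom == d)
    sig[idx, idx] <- sig[idx, idx] + outer(ls[idx], ls[idx])
  }
  diag(sig) <- 1
  dimnames(sig) <- list(config$variable_names, config$variable_names)
  sig
}

#' Simulate a synthetic longitudinal panel
#'
#' Draws a complete panel under the configured process, applies monotone
#' attrition (if any hazards are non-zero) and optional Likert
#' discretization, and attaches the generating truth as attribute
#' `"truth"`. Identical configs (same seed) produce identical panels.
#'
#' @param config A [dgp_config].
#' @return A [panel_data]; `attr(panel, "truth")` holds the true loadings /
#'   transition matrices and the pre-attrition values.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  n <- config$n_subjects; W <- config$n_waves
  vars <- config$variable_names; k <- length(vars)
  waves <- config$first_age + seq_len(W) - 1
  with_seed(config$seed, {
    vals <- array(NA_real_, c(n, W, k))
    if (config$dgp_kind == "common_cause") {
      ar <- config$factor_ar
      fac <- list(p = matrix(0, n, W), int = matrix(0, n, W),
                  ext = matrix(0, n, W))
      for (f in names(fac)) {
        phi <- ar[[f]]
        fac[[f]][, 1] <- stats::rnorm(n)
        for (w in 2:W) {
          fac[[f]][, w] <- phi * fac[[f]][, w - 1] +
            stats::rnorm(n, sd = sqrt(1 - phi^2))
        }
      }
      for (w in seq_len(W)) for (j in seq_len(k)) {
        dom <- config$domains[j]
        vals[, w, j] <- config$means[j] +
          config$general_loadings[j] * fac$p[, w] +
          config$specific_loadings[j] * fac[[dom]][, w] +
          stats::rnorm(n, sd = sqrt(config$residual_var[j]))
      }
      truth <- list(kind = "common_cause",
                    lambda_g = config$general_loadings,
                    lambda_s = config$specific_loadings,
                    theta = config$residual_var,
                    factor_ar = config$factor_ar,
                    implied_wave_cov = common_cause_implied_cov(config),
                    factors = fac)
    } else {
      A_list <- var_coefficients(config)
      L <- chol(config$innovation_cov)
      dom <- config$domains
      S0 <- matrix(config$baseline_cor[["cross"]], k, k)
      for (d in c("int", "ext")) {
        idx <- which(dom == d)
        S0[idx, idx] <- config$baseline_cor[["within"]]
      }
      diag(S0) <- 1
      y <- rmvn(n, rep(0, k), S0)
      vals[, 1, ] <- sweep(y, 2L, config$means, `+`)
      for (w in 2:W) {
        innov <- matrix(stats::rnorm(n * k), n, k) %*% L
        y <- y %*% t(A_list[[w - 1]]) + innov
        vals[, w, ] <- sweep(y, 2L, config$means, `+`)
      }
      truth <- list(kind = config$dgp_kind, A = A_list,
                    innovation_cov = config$innovation_cov,
                    baseline_cov = S0)
    }
    panel <- panel_data(vals, paste0("s", seq_len(n)), waves, vars)
    truth$complete_values <- vals
    if (any(config$attrition_hazard > 0)) {
      panel <- apply_attrition(panel, config$attrition_hazard,
                               mar_on = config$mar_on)
    }
    if (!is.null(config$likert)) {
      panel <- discretize_to_likert(panel, config$likert)
    }
    attr(panel, "truth") <- truth
    attr(panel, "config") <- config
    panel
  })
}

#' Apply monotone (survival-style) attrition to a panel
#'
#' Subjects drop out at each transition with the given hazard; once dropped,
#' all later waves are missing. The first wave is always observed. With
#' `mar_on` set, the dropout probability increases with the subject's
#' previous-wave standardized value on that variable through a logistic
#' link, producing missingness-at-random; otherwise dropout is completely at
#' random.
#'
#' @param panel A [panel_data].
#' @param hazards Per-transition hazards, scalar or length `n_waves - 1`,
#'   each in `[0, 1]`.
#' @param mar_on Optional variable name.
#' @param mar_strength Logit slope on the standardized previous-wave value
#'   (default 1).
#' @return The degraded [panel_data].
#' @export
apply_attrition <- function(panel, hazards, mar_on = NULL, mar_strength = 1) {
  n <- dim(panel)[1]; W <- dim(panel)[2]
  hazards <- rep_len(hazards, W - 1)
  stopifnot(all(hazards >= 0 & hazards <= 1))
  vals <- panel$values
  alive <- rep(TRUE, n)
  jm <- if (!is.null(mar_on)) match(mar_on, panel$variables) else NA_integer_
  if (!is.null(mar_on) && is.na(jm)) stop("mar_on variable not in panel")
  for (w in 2:W) {
    h <- hazards[w - 1]
    pdrop <- rep(h, n)
    if (!is.na(jm) && h > 0 && h < 1) {
      z <- vals[, w - 1, jm]
      z <- (z - mean(z, na.rm = TRUE)) / max(stats::sd(z, na.rm = TRUE), 1e-12)
      z[is.na(z)] <- 0
      pdrop <- stats::plogis(stats::qlogis(h) + mar_strength * z)
    }
    drop_now <- alive & (stats::runif(n) < pdrop)
    alive <- alive & !drop_now
    vals[!alive, w, ] <- NA_real_
  }
  out <- panel_data(vals, panel$subject_ids, panel$waves, panel$variables)
  attr(out, "truth") <- attr(panel, "truth")
  attr(out, "config") <- attr(panel, "config")
  out
}

#' Discretize a continuous panel to Likert categories
#'
#' Monotone binning: a value below the first threshold maps to category 0, a
#' value in `[t_c, t_{c+1})` to category `c`. Rank order within variable is
#' preserved.
#'
#' @param panel A [panel_data].
#' @param thresholds Strictly increasing numeric vector (shared across
#'   variables) or named list of per-variable threshold vectors.
#' @return The discretized [panel_data].
#' @export
discretize_to_likert <- function(panel, thresholds) {
  get_thr <- function(v) {
    thr <- if (is.list(thresholds)) thresholds[[v]] else thresholds
    if (is.null(thr)) stop("no thresholds for variable ", v)
    thr <- thr[is.finite(thr)]
    if (length(thr) > 1 && any(diff(thr) <= 0)) {
      stop("thresholds must be strictly increasing")
    }
    thr
  }
  vals <- panel$values
  for (j in seq_along(panel$variables)) {
    thr <- get_thr(panel$variables[j])
    x <- vals[, , j]
    if (length(thr)) {
      x[] <- findInterval(x, thr)
    } else {
      x[!is.na(x)] <- 0   # all thresholds at +-Inf: single category
    }
    vals[, , j] <- x
  }
  out <- panel_data(vals, panel$subject_ids, panel$waves, panel$variables)
  attr(out, "truth") <- attr(panel, "truth")
  attr(out, "config") <- attr(panel, "config")
  out
}

#' Read / write a DGP configuration as YAML or JSON
#'
#' @param config A [dgp_config].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path` invisibly; `dgp_config_from_file` returns the config.
#' @export
dgp_config_to_file <- function(config, path) {
  obj <- unclass(config)
  obj$innovation_cov <- as.data.frame(obj$innovation_cov)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname dgp_config_to_file
#' @export
dgp_config_from_file <- function(path) {
  o <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  dgp_config(
    dgp_kind = o$dgp_kind, n_subjects = o$n_subjects, n_waves = o$n_waves,
    first_age = o$first_age %||% 14,
    variable_names = unlist(o$variable_names),
    domains = stats::setNames(unlist(o$domains), unlist(o$variable_names)),
    general_loadings = stats::setNames(unlist(o$general_loadings),
                                       unlist(o$variable_names)),
    specific_loadings = stats::setNames(unlist(o$specific_loadings),
                                        unlist(o$variable_names)),
    factor_ar = unlist(o$factor_ar),
    coupling_start = o$coupling_start, coupling_end = o$coupling_end,
    within_ar = o$within_ar, within_domain_coupling = o$within_domain_coupling,
    innovation_cov = as.matrix(as.data.frame(o$innovation_cov)),
    baseline_cor = unlist(o$baseline_cor),
    means = stats::setNames(unlist(o$means), unlist(o$variable_names)),
    attrition_hazard = unlist(o$attrition_hazard),
    mar_on = o$mar_on, likert = o$likert, seed = o$seed
  )
}
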