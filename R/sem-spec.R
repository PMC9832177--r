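# Declarative covariance-structure model specification.
#
# A model is written in its LISREL-style matrix pattern form:
#   Sigma(theta) = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' + Theta
#   mu(theta)    = nu + Lambda (I - B)^-1 alpha
# Every cell of Lambda/B/Psi/Theta/nu/alpha is either fixed to a numeric
# value or free, carrying a parameter label; cells sharing a label are
# constrained equal.

new_pattern <- function(value, label) {
  stopifnot(identical(dim(value), dim(label)) ||
              (is.null(dim(value)) && length(value) == length(label)))
  list(value = value, label = label)
}

# Build a pattern matrix where everything is fixed at 0.
fixed_pattern <- function(nr, nc, dn = NULL) {
  list(value = matrix(0, nr, nc, dimnames = dn),
       label = matrix("", nr, nc, dimnames = dn))
}

#' Specify a latent-variable covariance-structure model
#'
#' Each of `lambda`, `beta`, `psi`, `theta` is supplied as a list with
#' elements `value` (numeric matrix of fixed values / start hints) and
#' `label` (character matrix, `""` marks a fixed cell, any other string a
#' free parameter). `nu` and `alpha` are the analogous vectors for observed
#' intercepts and latent means. Cells sharing a label are constrained equal.
#' Convenience: missing components default to all-fixed-at-zero (`psi`,
#' `theta` to zero matrices, `nu` free per observed variable, `alpha` fixed
#' at 0).
#'
#' @param obs Character vector of observed variable names.
#' @param lat Character vector of latent variable names.
#' @param lambda Loading pattern (`length(obs)` x `length(lat)`).
#' @param beta Latent regression pattern (`lat` x `lat`), row regressed on
#'   column; must be acyclic.
#' @param psi Latent (residual) covariance pattern, symmetric.
#' @param theta Observed residual covariance pattern, symmetric.
#' @param nu Observed intercept pattern (vectors `value`, `label`).
#' @param alpha Latent mean pattern.
#' @param meanstructure Model the mean vector (default `TRUE`).
#' @return An object of class `sem_spec`.
#' @export
sem_spec <- function(obs, lat, lambda, beta = NULL, psi = NULL, theta = NULL,
                     nu = NULL, alpha = NULL, meanstructure = TRUE) {
  k <- length(obs); m <- length(lat)
  stopifnot(k > 0, m > 0, !anyDuplicated(obs), !anyDuplicated(lat))
  beta <- beta %||% fixed_pattern(m, m)
  psi <- psi %||% fixed_pattern(m, m)
  theta <- theta %||% fixed_pattern(k, k)
  if (is.null(nu)) {
    nu <- list(value = rep(0, k), label = paste0("nu_", obs))
  }
  alpha <- alpha %||% list(value = rep(0, m), label = rep("", m))
  chk_dim <- function(p, nr, nc, nm) {
    if (!identical(dim(p$value), as.integer(c(nr, nc))) ||
        !identical(dim(p$label), as.integer(c(nr, nc)))) {
      stop(nm, " pattern has wrong dimensions")
    }
  }
  chk_dim(lambda, k, m, "lambda"); chk_dim(beta, m, m, "beta")
  chk_dim(psi, m, m, "psi"); chk_dim(theta, k, k, "theta")
  chk_sym <- function(p, nm) {
    if (!is_symmetric(p$value) || any(p$label != t(p$label))) {
      stop(nm, " pattern must be symmetric")
    }
  }
  chk_sym(psi, "psi"); chk_sym(theta, "theta")
  if (length(nu$value) != k || length(nu$label) != k) stop("nu has wrong length")
  if (length(alpha$value) != m || length(alpha$label) != m) {
    stop("alpha has wrong length")
  }
  if (any(diag(beta$value) != 0) || any(nzchar(diag(beta$label)))) {
    stop("beta diagonal must be fixed at 0")
  }
  # Acyclicity of the structural part.
  adj <- (beta$value != 0) | nzchar(beta$label)   # row <- col
  if (any(adj)) {
    g <- igraph::graph_from_adjacency_matrix(t(adj) * 1, mode = "directed")
    if (!igraph::is_dag(g)) stop("latent regressions must be acyclic")
  }
  dimnames(lambda$value) <- dimnames(lambda$label) <- list(obs, lat)
  dimnames(beta$value) <- dimnames(beta$label) <- list(lat, lat)
  dimnames(psi$value) <- dimnames(psi$label) <- list(lat, lat)
  dimnames(theta$value) <- dimnames(theta$label) <- list(obs, obs)
  spec <- structure(
    list(obs = obs, lat = lat, lambda = lambda, beta = beta, psi = psi,
         theta = theta, nu = nu, alpha = alpha,
         meanstructure = isTRUE(meanstructure)),
    class = "sem_spec")
  # Identification heuristics: every latent needs a fixed scale.
  for (j in seq_len(m)) {
    has_fixed_var <- !nzchar(psi$label[j, j]) && psi$value[j, j] > 0
    has_fixed_loading <- any(!nzchar(lambda$label[, j]) & lambda$value[, j] != 0)
    has_incoming <- any(adj[j, ])
    if (!has_fixed_var && !has_fixed_loading && !has_incoming) {
      stop("latent '", lat[j],
           "' has neither a fixed variance nor a fixed loading")
    }
  }
  spec
}

#' @export
print.sem_spec <- function(x, ...) {
  pt <- spec_param_table(x)
  cat(sprintf("<sem_spec> %d observed, %d latent, %d free parameters (%d labels)\n",
              length(x$obs), length(x$lat), nrow(pt$cells), length(pt$labels)))
  invisible(x)
}

# Enumerate free cells and map labels -> cells. Symmetric matrices contribute
# lower-triangle cells only. Returns list(labels, cells data.frame, lower).
spec_param_table <- function(spec) {
  rows <- list()
  add <- function(mat, nm) {
    idx <- which(nzchar(mat$label))
    if (length(idx)) {
      rows[[length(rows) + 1]] <<- data.frame(
        mat = nm, i = idx, j = 0L, label = mat$label[idx],
        start = mat$value[idx], stringsAsFactors = FALSE)
    }
  }
  add2 <- function(mat, nm, sym = FALSE) {
    lab <- mat$label
    idx <- which(lab != "", arr.ind = TRUE)
    if (sym && nrow(idx)) idx <- idx[idx[, 1] >= idx[, 2], , drop = FALSE]
    if (nrow(idx)) {
      rows[[length(rows) + 1]] <<- data.frame(
        mat = nm, i = idx[, 1], j = idx[, 2], label = lab[idx],
        start = mat$value[idx], stringsAsFactors = FALSE)
    }
  }
  add2(spec$lambda, "lambda"); add2(spec$beta, "beta")
  add2(spec$psi, "psi", sym = TRUE); add2(spec$theta, "theta", sym = TRUE)
  add(spec$nu, "nu")
  add(spec$alpha, "alpha")
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mat = character(), i = integer(), j = integer(),
               label = character(), start = numeric())
  labels <- unique(cells$label)
  # Lower bound 0 only for labels confined to psi/theta diagonals (variances).
  lower <- vapply(labels, function(l) {
    sub <- cells[cells$label == l, , drop = FALSE]
    all(sub$mat %in% c("psi", "theta") & sub$i == sub$j)
  }, logical(1))
  list(labels = labels, cells = cells,
       lower = ifelse(lower, 0, -Inf))
}

#' Count free parameters of a specification
#' @param spec A [sem_spec].
#' @return Integer number of distinct free parameter labels.
#' @export
n_free_params <- function(spec) length(spec_param_table(spec)$labels)

# Fill pattern matrices from a named parameter vector.
spec_matrices <- function(spec, theta_vec) {
  fill <- function(mat, sym = FALSE) {
    v <- mat$value
    idx <- which(nzchar(mat$label))
    if (length(idx)) v[idx] <- theta_vec[mat$label[idx]]
    if (sym) v[upper.tri(v)] <- t(v)[upper.tri(v)]
    v
  }
  lambda <- fill(spec$lambda)
  beta <- fill(spec$beta)
  psi <- fill(spec$psi, sym = TRUE)
  theta <- fill(spec$theta, sym = TRUE)
  nu <- spec$nu$value
  idx <- which(nzchar(spec$nu$label))
  if (length(idx)) nu[idx] <- theta_vec[spec$nu$label[idx]]
  alpha <- spec$alpha$value
  idx <- which(nzchar(spec$alpha$label))
  if (length(idx)) alpha[idx] <- theta_vec[spec$alpha$label[idx]]
  list(lambda = lambda, beta = beta, psi = psi, theta = theta,
       nu = nu, alpha = alpha)
}

# Model-implied moments from filled matrices.
implied_moments <- function(mats) {
  m <- nrow(mats$beta)
  M <- if (any(mats$beta != 0)) solve(diag(m) - mats$beta) else diag(m)
  G <- mats$lambda %*% M
  E <- M %*% mats$psi %*% t(M)
  sigma <- mats$lambda %*% E %*% t(mats$lambda) + mats$theta
  sigma <- (sigma + t(sigma)) / 2
  mu <- as.vector(mats$nu + G %*% mats$alpha)
  list(sigma = sigma, mu = mu, M = M, G = G, E = E)
}

#' Serialize a model specification to JSON
#'
#' @param spec A [sem_spec].
#' @param path Output path.
#' @return `path` invisibly; `sem_spec_from_json` returns the [sem_spec].
#' @export
sem_spec_to_json <- function(spec, path) {
  enc <- function(p) list(value = p$value, label = p$label)
  obj <- list(obs = spec$obs, lat = spec$lat,
              lambda = enc(spec$lambda), beta = enc(spec$beta),
              psi = enc(spec$psi), theta = enc(spec$theta),
              nu = list(value = spec$nu$value, label = spec$nu$label),
              alpha = list(value = spec$alpha$value, label = spec$alpha$label),
              meanstructure = spec$meanstructure)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname sem_spec_to_json
#' @export
sem_spec_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(p) list(value = as.matrix(p$value),
                          label = as.matrix(p$label))
  sem_spec(unlist(o$obs), unlist(o$lat), dec(o$lambda), dec(o$beta),
           dec(o$psi), dec(o$theta),
           list(value = as.numeric(o$nu$value), label = as.character(o$nu$label)),
           list(value = as.numeric(o$alpha$value),
                label = as.character(o$alpha$label)),
           meanstructure = isTRUE(o$meanstructure))
}

# One-factor measurement model with standardized factor (variance fixed 1).
one_factor_spec <- function(items) {
  k <- length(items)
  lambda <- list(value = matrix(0.5, k, 1),
                 label = matrix(paste0("l_", items), k, 1))
  psi <- list(value = matrix(1, 1, 1), label = matrix("", 1, 1))
  theta <- list(value = diag(0.5, k),
                label = diag_label(paste0("th_", items)))
  sem_spec(items, "f", lambda, psi = psi, theta = theta)
}

# Diagonal label matrix helper.
diag_label <- function(labels) {
  k <- length(labels)
  m <- matrix("", k, k)
  diag(m) <- labels
  m
}
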