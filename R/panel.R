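# Longitudinal panel container and preparation steps: reading/writing panels,
# proportion-of-maximum rescaling, composite construction, and scale-level
# model-based reliability.

#' Construct a longitudinal panel dataset
#'
#' A `panel_data` object holds severity scores indexed subject x wave x
#' variable together with an observedness mask. Waves are integer age labels
#' (years); the design is annual assessment so waves must be strictly
#' increasing.
#'
#' @param values Numeric array `(n_subjects, n_waves, n_variables)`; `NA`
#'   allowed where unobserved.
#' @param subject_ids Unique subject identifiers (coerced to character).
#' @param waves Strictly increasing integer age labels, length `>= 2`.
#' @param variables Measure names.
#' @param mask Optional logical array of the same shape; defaults to
#'   `!is.na(values)`. The mask must be `FALSE` wherever `values` is `NA`.
#' @return An object of class `panel_data`.
#' @export
panel_data <- function(values, subject_ids, waves, variables, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  n <- dim(values)[1]; W <- dim(values)[2]; k <- dim(values)[3]
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("subject_ids length must match dim 1 of values")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  waves <- as.integer(waves)
  if (length(waves) != W) stop("waves length must match dim 2 of values")
  if (W < 2) stop("a panel needs at least 2 waves")
  if (any(diff(waves) <= 0)) stop("waves must be strictly increasing")
  if (length(variables) != k) stop("variables length must match dim 3 of values")
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  mask <- array(as.logical(mask), dim(values))
  if (any(mask & is.na(values))) stop("mask is TRUE on an undefined (NA) value")
  if (any(!is.finite(values[mask]))) stop("observed values must be finite")
  values[!mask] <- NA_real_
  dimnames(values) <- dimnames(mask) <-
    list(subject_ids, paste0("age", waves), variables)
  structure(
    list(values = values, mask = mask, subject_ids = subject_ids,
         waves = waves, variables = variables),
    class = "panel_data"
  )
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf(
    "<panel_data> %d subjects x %d waves (ages %d-%d) x %d variables; %.1f%% observed\n",
    length(x$subject_ids), length(x$waves), min(x$waves), max(x$waves),
    length(x$variables), 100 * mean(x$mask)))
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.panel_data <- function(x) dim(x$values)

#' Extract one wave of a panel as a subject x variable matrix
#'
#' @param panel A `panel_data` object.
#' @param wave Age label of the wave to extract.
#' @return Numeric matrix with `NA` for unobserved cells.
#' @export
panel_wave_matrix <- function(panel, wave) {
  w <- match(wave, panel$waves)
  if (is.na(w)) stop("wave ", wave, " not present in panel")
  m <- panel$values[, w, , drop = FALSE]
  dim(m) <- dim(panel$values)[c(1, 3)]
  dimnames(m) <- list(panel$subject_ids, panel$variables)
  m
}

#' Flatten a panel into a wide subject x (variable.wave) matrix
#'
#' Column order is wave-major: all variables at the first wave, then the next
#' wave, and so on. Column names are `<variable>.<age>`.
#'
#' @param panel A `panel_data` object.
#' @return Numeric matrix with one row per subject.
#' @export
panel_wide_matrix <- function(panel) {
  n <- dim(panel)[1]; W <- dim(panel)[2]; k <- dim(panel)[3]
  out <- matrix(NA_real_, n, W * k)
  cn <- character(W * k)
  for (w in seq_len(W)) {
    idx <- (w - 1) * k + seq_len(k)
    out[, idx] <- panel$values[, w, ]
    cn[idx] <- paste0(panel$variables, ".", panel$waves[w])
  }
  dimnames(out) <- list(panel$subject_ids, cn)
  out
}

#' Read a longitudinal panel from CSV
#'
#' Long format (canonical) expects one row per observed cell with columns for
#' subject, wave, variable and value; empty/NA value cells become unobserved.
#' Wide format expects one row per subject x wave with one column per
#' variable.
#'
#' @param path CSV file (UTF-8, header row).
#' @param layout `"long"` or `"wide"`.
#' @param schema Named list mapping roles to column names. For long:
#'   `subject`, `wave`, `variable`, `value`. For wide: `subject`, `wave`,
#'   and `variables` (character vector of value columns).
#' @return A [panel_data] object.
#' @examples
#' # a small synthetic demonstration panel ships with the package
#' f <- system.file("extdata", "synthetic_panel_long.csv", package = "pmutual")
#' read_panel(f, "long")
#' @export
read_panel <- function(path, layout = c("long", "wide"), schema = NULL) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    schema <- schema %||% list(subject = "subject", wave = "wave",
                               variable = "variable", value = "value")
    need <- unlist(schema[c("subject", "wave", "variable", "value")])
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns in CSV: ", paste(miss, collapse = ", "))
    long_to_panel(df[[schema$subject]], df[[schema$wave]],
                  df[[schema$variable]], df[[schema$value]])
  } else {
    schema <- schema %||% list(subject = "subject", wave = "wave",
                               variables = setdiff(names(df), c("subject", "wave")))
    vars <- schema$variables
    miss <- setdiff(c(schema$subject, schema$wave, vars), names(df))
    if (length(miss)) stop("missing columns in CSV: ", paste(miss, collapse = ", "))
    sub <- rep(df[[schema$subject]], times = length(vars))
    wav <- rep(df[[schema$wave]], times = length(vars))
    var <- rep(vars, each = nrow(df))
    val <- unlist(df[vars], use.names = FALSE)
    long_to_panel(sub, wav, var, val)
  }
}

# Shared assembly for both layouts; validates duplicates and numeric cells.
long_to_panel <- function(subject, wave, variable, value) {
  key <- paste(subject, wave, variable, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup) {
    stop(sprintf("duplicate (subject, wave, variable) row: (%s, %s, %s)",
                 subject[dup], wave[dup], variable[dup]))
  }
  if (is.character(value)) {
    blank <- !nzchar(trimws(value))
    num <- suppressWarnings(as.numeric(value))
    bad <- which(!blank & is.na(num) & !is.na(value) &
                   !(trimws(value) %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s in row %d", dQuote(value[bad[1]]), bad[1]))
    }
    value <- num
  }
  value <- as.numeric(value)
  subject_ids <- unique(as.character(subject))
  waves <- sort(unique(as.integer(wave)))
  variables <- unique(as.character(variable))
  vals <- array(NA_real_,
                c(length(subject_ids), length(waves), length(variables)))
  i <- match(as.character(subject), subject_ids)
  j <- match(as.integer(wave), waves)
  l <- match(as.character(variable), variables)
  vals[cbind(i, j, l)] <- value
  panel_data(vals, subject_ids, waves, variables)
}

#' Write a panel to long CSV (with provenance sidecar)
#'
#' Writes one row per cell (unobserved cells with empty value) plus a sidecar
#' JSON file `<path>.meta.json` recording the content hash and options, so a
#' written panel can be audited and round-tripped.
#'
#' @param panel A [panel_data] object.
#' @param path Output CSV path.
#' @param observed_only If `TRUE` (default) only observed cells are written.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, observed_only = TRUE) {
  n <- dim(panel)[1]; W <- dim(panel)[2]; k <- dim(panel)[3]
  df <- data.frame(
    subject = rep(panel$subject_ids, times = W * k),
    wave = rep(rep(panel$waves, each = n), times = k),
    variable = rep(panel$variables, each = n * W),
    value = as.vector(panel$values),
    stringsAsFactors = FALSE
  )
  if (observed_only) df <- df[as.vector(panel$mask), , drop = FALSE]
  # %.17g keeps doubles bit-exact across the write -> read round trip
  df$value <- ifelse(is.na(df$value), NA, sprintf("%.17g", df$value))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(
    format = "pmutual panel long CSV",
    n_subjects = n, n_waves = W, n_variables = k,
    waves = panel$waves, variables = panel$variables,
    observed_only = observed_only,
    content_md5 = unname(tools::md5sum(path)),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Define a symptom scale
#'
#' Declares the items, Likert bounds and scoring rule of one instrument scale.
#'
#' @param scale_name Scale label (e.g. `"gad"`).
#' @param item_names Non-empty character vector of item names.
#' @param response_min,response_max Per-item Likert bounds (recycled if scalar).
#' @param scoring_rule `"sum"` or `"mean"`.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(scale_name, item_names, response_min, response_max,
                             scoring_rule = c("sum", "mean")) {
  scoring_rule <- match.arg(scoring_rule)
  if (!length(item_names)) stop("item list must be non-empty")
  response_min <- rep_len(as.numeric(response_min), length(item_names))
  response_max <- rep_len(as.numeric(response_max), length(item_names))
  if (any(response_max <= response_min)) {
    stop("response_max must exceed response_min for every item")
  }
  structure(list(scale_name = scale_name, item_names = item_names,
                 response_min = response_min, response_max = response_max,
                 scoring_rule = scoring_rule),
            class = "scale_definition")
}

#' Read / write scale definitions as JSON
#'
#' @param path JSON file path.
#' @return `read_scale_definitions` returns a list of [scale_definition]
#'   objects; `write_scale_definitions` returns `path` invisibly.
#' @export
read_scale_definitions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    scale_definition(r$scale_name, r$item_names, r$response_min,
                     r$response_max, r$scoring_rule)
  })
}

#' @rdname read_scale_definitions
#' @param definitions List of [scale_definition] objects.
#' @export
write_scale_definitions <- function(definitions, path) {
  jsonlite::write_json(lapply(definitions, unclass), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Proportion-of-maximum rescaling
#'
#' Maps bounded Likert responses onto a common 0-1 metric via
#' `(x - min) / (max - min)`, so items with different response ranges (e.g. a
#' 0-3 symptom item and a 0-2 screener item) become comparable. Missing values
#' stay missing; out-of-bounds values are treated as data-entry errors.
#'
#' @param item_values Numeric vector (or subject x item matrix whose columns
#'   align with `definition$item_names`).
#' @param definition A [scale_definition].
#' @return Rescaled values in `[0, 1]`, same shape as the input.
#' @export
poms_rescale <- function(item_values, definition) {
  m <- if (is.matrix(item_values)) item_values else
    matrix(item_values, ncol = length(definition$item_names))
  if (ncol(m) != length(definition$item_names)) {
    stop("item_values columns must match the scale's item list")
  }
  lo <- definition$response_min; hi <- definition$response_max
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.na(m[, j]) & (m[, j] < lo[j] | m[, j] > hi[j]))
    if (length(bad)) {
      stop(sprintf("value %g out of declared bounds [%g, %g] for item '%s'",
                   m[bad[1], j], lo[j], hi[j], definition$item_names[j]))
    }
    m[, j] <- (m[, j] - lo[j]) / (hi[j] - lo[j])
  }
  if (is.matrix(item_values)) m else as.vector(m)
}

#' Build composite severity scores from item-level panels
#'
#' Forms one composite per scale at every wave: sum-rule composites are sums
#' over observed items (the usual symptom-count convention); mean-rule
#' composites are item means (used where instruments change item counts across
#' ages, e.g. conduct/antisocial traits, or where substances are averaged).
#' A composite is set missing when more than `max_missing_frac` of its items
#' are unobserved at that wave; below that threshold, sums and means are taken
#' over the observed items.
#'
#' @param panel Item-level [panel_data].
#' @param recipes List of [scale_definition] objects.
#' @param max_missing_frac Largest tolerated fraction of missing items
#'   (default 0.25).
#' @return Composite-level [panel_data] with one variable per recipe.
#' @export
build_composites <- function(panel, recipes, max_missing_frac = 0.25) {
  n <- dim(panel)[1]; W <- dim(panel)[2]
  out <- array(NA_real_, c(n, W, length(recipes)))
  nm <- vapply(recipes, function(r) r$scale_name, character(1))
  for (r in seq_along(recipes)) {
    rec <- recipes[[r]]
    miss <- setdiff(rec$item_names, panel$variables)
    if (length(miss)) {
      stop("recipe '", rec$scale_name, "' references unknown item(s): ",
           paste(miss, collapse = ", "))
    }
    idx <- match(rec$item_names, panel$variables)
    k <- length(idx)
    for (w in seq_len(W)) {
      vals <- panel$values[, w, idx, drop = FALSE]
      dim(vals) <- c(n, k)
      nobs <- rowSums(!is.na(vals))
      ok <- (k - nobs) / k <= max_missing_frac & nobs > 0
      comp <- rep(NA_real_, n)
      if (rec$scoring_rule == "sum") {
        comp[ok] <- rowSums(vals[ok, , drop = FALSE], na.rm = TRUE)
      } else {
        comp[ok] <- rowMeans(vals[ok, , drop = FALSE], na.rm = TRUE)
      }
      out[, w, r] <- comp
    }
  }
  panel_data(out, panel$subject_ids, panel$waves, nm)
}

#' Coefficient omega for one scale
#'
#' Model-based internal consistency: fits a one-factor model to the item
#' covariance matrix by maximum likelihood and returns
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)`.
#'
#' @param item_data Numeric subject x item matrix (complete rows are used).
#' @return List with `omega`, `loadings`, `residuals`, `converged`, `n_used`
#'   and `flags` (character vector of diagnostics; empty when clean).
#' @export
scale_omega <- function(item_data) {
  item_data <- as.matrix(item_data)
  k <- ncol(item_data)
  flags <- character(0)
  if (k < 3) stop("omega needs at least 3 items")
  cc <- stats::complete.cases(item_data)
  n <- sum(cc)
  if (n < 50) flags <- c(flags, sprintf("only %d complete rows (<50)", n))
  x <- item_data[cc, , drop = FALSE]
  items <- colnames(x) %||% paste0("item", seq_len(k))
  colnames(x) <- items
  spec <- one_factor_spec(items)
  fit <- sem_fit(spec, x, missing = "listwise", se = FALSE)
  if (!fit$converged) {
    flags <- c(flags, "one-factor ML fit did not converge")
    return(list(omega = NA_real_, loadings = NULL, residuals = NULL,
                converged = FALSE, n_used = n, flags = flags))
  }
  lam <- fit$matrices$lambda[, 1]
  th <- diag(fit$matrices$theta)
  # Resolve the sign indeterminacy of the factor.
  if (sum(lam) < 0) lam <- -lam
  omega <- sum(lam)^2 / (sum(lam)^2 + sum(th))
  list(omega = omega, loadings = stats::setNames(lam, items),
       residuals = stats::setNames(th, items),
       converged = TRUE, n_used = n, flags = flags)
}
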