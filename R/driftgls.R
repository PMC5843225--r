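## Statistical core: migratory distance regressed on transformed allele
## proportions by Gaussian maximum likelihood, with an optional
## pseudo-correlation matrix capturing shared genetic drift between
## populations, AIC model search over marker interactions, and an
## empirical inflation-factor multiple-testing correction.

#' Arcsine-square-root transform of an allelic proportion
#'
#' Variance-stabilizing transform for proportions: `asin(sqrt(p))`,
#' mapping \[0, 1\] to \[0, pi/2\] radians.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s) in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Drift pseudo-correlation from squared genetic distances
#'
#' Maps a squared genetic-distance matrix D2 to a pseudo-correlation
#' `R[i,j] = (max(D2) - D2[i,j]) / max(D2)`: unit diagonal, 0 at the
#' maximal distance. The transform does not guarantee positive
#' definiteness; if the smallest eigenvalue falls below `1e-10`, a ridge
#' of `1e-8` is added to the diagonal and the matrix renormalized to
#' unit diagonal, with the ridge recorded in the `"ridge"` attribute.
#'
#' @param D A `drift_distance_matrix` (or plain symmetric matrix with
#'   zero diagonal).
#' @return A `drift_correlation` matrix (entries in \[0, 1\]).
#' @export
drift_to_correlation <- function(D) {
  if (!inherits(D, "drift_distance_matrix"))
    D <- drift_distance_matrix(as.matrix(D))
  if (nrow(D) < 2L) stop("need at least 2 populations")
  m <- max(D)
  if (m <= 0) stop("degenerate distances: max(D2) must be positive")
  R <- (m - unclass(D)) / m
  ridge <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    ridge <- 1e-8
    R <- R + diag(ridge, nrow(R))
    R <- stats::cov2cor(R)
  }
  structure(R, class = c("drift_correlation", class(matrix())), ridge = ridge)
}

#' Specify a cline regression model
#'
#' A model is a set of main-effect markers plus interaction terms
#' (unordered marker tuples of size 2 or 3). Interactions may reference
#' markers that are not main effects; whether the search permits that is
#' controlled in [enumerate_models()].
#'
#' @param mains Character vector of marker ids (may be empty if
#'   `interactions` is not).
#' @param interactions List of character vectors, each of length 2 or 3.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(mains = character(), interactions = list()) {
  mains <- as.character(mains)
  interactions <- lapply(interactions, function(t) sort(as.character(t)))
  if (length(mains) == 0L && length(interactions) == 0L)
    stop("empty model")
  if (anyDuplicated(mains)) stop("duplicate main effects")
  sizes <- lengths(interactions)
  if (any(sizes < 2L | sizes > 3L))
    stop("interactions must involve 2 or 3 markers")
  labels <- vapply(interactions, paste, character(1), collapse = ":")
  if (anyDuplicated(labels)) stop("duplicate interaction terms")
  structure(list(mains = mains, interactions = interactions),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste(c(x$mains, vapply(x$interactions, paste, character(1), collapse = ":")),
        collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Build the design matrix and response for a cline model
#'
#' One intercept column, one column `asin(sqrt(p))` per main-effect
#' marker, and interaction columns as element-wise products of the
#' transformed marker columns. The response is the migratory distance in
#' km. Rows with a missing value in any used marker are dropped
#' (complete-case) and counted in the `"dropped"` attribute. Markers
#' listed in `complement` enter as `1 - p` before the transform (used
#' where the counted allele of the published table is the complement of
#' the one the published regression modeled).
#'
#' @param table A `population_table`.
#' @param spec A `model_spec` (or a character vector of main-effect
#'   markers).
#' @param complement Character vector of markers to complement.
#' @return List with design matrix `X` (first column intercept), response
#'   `y`, term labels `terms`, and the number of `dropped` rows.
#' @export
build_design <- function(table, spec, complement = character()) {
  if (is.character(spec)) spec <- model_spec(mains = spec)
  stopifnot(inherits(spec, "model_spec"))
  used <- unique(c(spec$mains, unlist(spec$interactions)))
  missing_m <- setdiff(used, markers(table))
  if (length(missing_m))
    stop("markers not in table: ", paste(missing_m, collapse = ", "))
  df <- as.data.frame(table)
  keep <- stats::complete.cases(df[, used, drop = FALSE])
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  trans <- vapply(used, function(m) {
    p <- df[[m]]
    if (m %in% complement) p <- 1 - p
    arcsine_sqrt(p)
  }, numeric(nrow(df)))
  trans <- matrix(trans, nrow = nrow(df), dimnames = list(NULL, used))
  cols <- list(`(Intercept)` = rep(1, nrow(df)))
  for (m in spec$mains) cols[[m]] <- trans[, m]
  for (t in spec$interactions)
    cols[[paste(t, collapse = ":")]] <- apply(trans[, t, drop = FALSE], 1, prod)
  X <- do.call(cbind, cols)
  for (j in seq_len(ncol(X))[-1L])
    if (stats::var(X[, j]) == 0)
      stop("zero-variance design column for term '", colnames(X)[j], "'")
  list(X = X, y = df$distance_km, terms = colnames(X), dropped = dropped)
}

#' Generalized least squares by Gaussian maximum likelihood
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * R)`, maximizing the full
#' (not restricted) Gaussian log-likelihood. Closed form:
#' `beta = (X'R^-1 X)^-1 X'R^-1 y`, `sigma2 = e'R^-1 e / n` (ML,
#' n-denominator), `loglik = -n/2 (log(2 pi sigma2) + 1) - log det(R)/2`.
#' Standard errors come from `sigma2 (X'R^-1 X)^-1`; p-values are
#' two-sided Wald z. `AIC = -2 loglik + 2 (k + 1)` with `k` mean
#' parameters plus the variance.
#'
#' @param X Design matrix (including intercept), or the list returned by
#'   [build_design()].
#' @param y Response (ignored when `X` is a `build_design()` list).
#' @param R Error correlation (or covariance-structure, up to scale)
#'   matrix, or `NULL` for the identity (ordinary least squares, to
#'   which the ML fit then reduces).
#' @return An object of class `gls_fit`: `coefficients`, `se`, `z`,
#'   `p_value`, `sigma2`, `loglik`, `aic`, `n`, `k`, `residuals`,
#'   `ridge` (ridge recorded on `R`, if any), `terms`.
#' @export
gls_fit <- function(X, y = NULL, R = NULL) {
  if (is.list(X) && !is.null(X$X)) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more observations than parameters (n > k)")
  ridge <- 0
  if (is.null(R)) {
    Xs <- X; ys <- y; logdetR <- 0
  } else {
    R <- as.matrix(R)
    stopifnot(nrow(R) == n, ncol(R) == n)
    ridge <- attr(R, "ridge") %||% 0
    U <- tryCatch(chol(R), error = function(e)
      stop("correlation matrix not positive definite"))
    Xs <- backsolve(U, X, transpose = TRUE)
    ys <- backsolve(U, y, transpose = TRUE)
    logdetR <- 2 * sum(log(diag(U)))
  }
  XtX <- crossprod(Xs)
  qrX <- qr(XtX)
  if (qrX$rank < k) stop("collinear design")
  beta <- drop(solve(qrX, crossprod(Xs, ys)))
  e <- drop(y - X %*% beta)
  es <- drop(ys - Xs %*% beta)
  if (stats::var(y) == 0)
    stop("degenerate fit: constant response")
  rss <- sum(es^2)
  sigma2 <- rss / n
  if (sigma2 < 1e-12 * mean(y^2)) {
    # exact (noiseless) fit: the Gaussian likelihood is unbounded; the
    # coefficients remain well defined, inference quantities collapse
    sigma2 <- 0
    loglik <- Inf
    se <- rep(0, k)
    z <- ifelse(beta == 0, 0, sign(beta) * Inf)
    p <- as.numeric(beta == 0)
  } else {
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdetR / 2
    covb <- sigma2 * solve(qrX)
    se <- sqrt(diag(covb))
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  names(beta) <- names(se) <- names(z) <- names(p) <- colnames(X)
  structure(list(coefficients = beta, se = se, z = z, p_value = p,
                 sigma2 = sigma2, loglik = loglik,
                 aic = -2 * loglik + 2 * (k + 1), n = n, k = k,
                 residuals = e, ridge = ridge, terms = colnames(X)),
            class = "gls_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("Gaussian-ML GLS fit: n = %d, k = %d, loglik = %.3f, AIC = %.3f\n",
              x$n, x$k, x$loglik, x$aic))
  tab <- data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p_value)
  print(tab, digits = 6)
  invisible(x)
}

#' Fit one cline model on a population table
#'
#' Convenience wrapper: [build_design()] then [gls_fit()], enforcing the
#' complete-case minimum sample size `n >= k + 2`.
#'
#' @inheritParams build_design
#' @param R Error correlation matrix (`NULL` = identity). Must cover the
#'   full table; it is subset to the complete-case rows.
#' @return A `gls_fit` with the `model_spec` attached as `$spec`.
#' @export
fit_cline_model <- function(table, spec, R = NULL, complement = character()) {
  if (is.character(spec)) spec <- model_spec(mains = spec)
  d <- build_design(table, spec, complement = complement)
  if (!is.null(R)) {
    stopifnot(nrow(R) == nrow(table))
    if (d$dropped > 0) {
      used <- unique(c(spec$mains, unlist(spec$interactions)))
      keep <- stats::complete.cases(as.data.frame(table)[, used, drop = FALSE])
      R <- R[keep, keep, drop = FALSE]
    }
  }
  if (length(d$y) < ncol(d$X) + 2L)
    stop("too few complete cases: need n >= k + 2")
  fit <- gls_fit(d$X, d$y, R)
  fit$spec <- spec
  fit$dropped <- d$dropped
  fit
}

#' Enumerate candidate models over a marker set
#'
#' All non-empty subsets of main effects, each optionally augmented with
#' any subset of the interactions (order 2, and order 3 when
#' `max_order = 3`) among its members. With `require_mains = FALSE` the
#' hierarchy is not enforced: models are arbitrary non-empty subsets of
#' the full term universe (all mains plus all interactions over the
#' marker set), which permits an interaction without its main effects,
#' as published best models sometimes do. Ordering is deterministic.
#'
#' @param markers Character vector (1 to 9 markers).
#' @param max_order Highest interaction order, 2 or 3.
#' @param require_mains Enforce that every interaction's markers appear
#'   as main effects (default `TRUE`).
#' @param max_models Guard against combinatorial explosion.
#' @return List of `model_spec`s.
#' @export
enumerate_models <- function(markers, max_order = 2, require_mains = TRUE,
                             max_models = 5e5) {
  stopifnot(length(markers) >= 1L, length(markers) <= 9L,
            max_order %in% c(2L, 3L))
  all_inter <- function(S) {
    out <- list()
    if (length(S) >= 2L)
      out <- c(out, utils::combn(S, 2L, simplify = FALSE))
    if (max_order >= 3L && length(S) >= 3L)
      out <- c(out, utils::combn(S, 3L, simplify = FALSE))
    out
  }
  subsets <- function(x) {  # all subsets incl. empty, deterministic order
    n <- length(x)
    lapply(seq_len(2^n) - 1L, function(mask)
      x[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
  }
  models <- list()
  if (require_mains) {
    main_sets <- subsets(markers)[-1L]  # non-empty
    for (S in main_sets) {
      ints <- all_inter(S)
      n_int <- length(ints)
      if (length(models) + 2^n_int > max_models)
        stop("model space exceeds max_models = ", max_models)
      for (mask in seq_len(2^n_int) - 1L) {
        sel <- if (n_int == 0L) list() else
          ints[bitwAnd(mask, bitwShiftL(1L, seq_len(n_int) - 1L)) > 0L]
        models[[length(models) + 1L]] <- model_spec(S, sel)
      }
    }
  } else {
    ints <- all_inter(markers)
    terms <- c(as.list(markers), ints)
    n_t <- length(terms)
    if (2^n_t - 1 > max_models)
      stop("model space exceeds max_models = ", max_models)
    for (mask in seq_len(2^n_t - 1L)) {
      sel <- terms[bitwAnd(mask, bitwShiftL(1L, seq_len(n_t) - 1L)) > 0L]
      is_main <- lengths(sel) == 1L
      models[[length(models) + 1L]] <-
        model_spec(unlist(sel[is_main]), sel[!is_main])
    }
  }
  models
}

#' Select the best fit by AIC
#'
#' Minimal AIC; ties broken by fewer mean parameters `k`, then by
#' position in the input list (which is the deterministic enumeration
#' order).
#'
#' @param fits Non-empty list of `gls_fit`s.
#' @return The winning `gls_fit`.
#' @export
select_best_aic <- function(fits) {
  if (length(fits) == 0L) stop("no fits to select from")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  fits[[order(aic, k, seq_along(fits))[1L]]]
}

#' Empirical inflation factor from null p-values
#'
#' The ratio between the proportion of null fits significant at `alpha`
#' and `alpha` itself. A well-calibrated test on true nulls gives a
#' factor near 1; drift-confounded naive tests give factors well above 1.
#'
#' @param null_pvalues Numeric vector of p-values from null-marker fits.
#' @param alpha Significance level (default 0.05).
#' @return The factor (nonnegative scalar).
#' @export
inflation_factor <- function(null_pvalues, alpha = 0.05) {
  if (length(null_pvalues) == 0L) stop("need at least one null p-value")
  if (any(is.na(null_pvalues)) || any(null_pvalues < 0 | null_pvalues > 1))
    stop("p-values must lie in [0, 1]")
  mean(null_pvalues < alpha) / alpha
}

#' Inflation-corrected p-values
#'
#' Each p-value is multiplied by the factor and capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @param factor Nonnegative inflation factor.
#' @return Corrected p-values, `min(1, p * factor)`.
#' @export
correct_pvalues <- function(p, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 0)
  pmin(1, p * factor)
}

#' Model scan with AIC ranking and inflation-corrected p-values
#'
#' Fits every model enumerated over `scan_markers` (see
#' [enumerate_models()]), ranks by AIC, and corrects all term p-values by
#' the empirical inflation factor computed from `n_null` null-marker
#' univariate fits produced by `null_generator`.
#'
#' @param table A `population_table`.
#' @param scan_markers Markers to scan (default: all in `table`).
#' @param R Drift correlation matrix or `NULL` for identity.
#' @param max_order Interaction order (2 or 3).
#' @param null_generator Function `(table, n_markers, seed)` returning an
#'   `n_pops x n_markers` matrix of null frequency columns (e.g.
#'   [simulate_null_markers()]); `NULL` skips the correction.
#' @param n_null Number of null markers (default 10000).
#' @param seed Seed forwarded to the generator (required with one).
#' @param alpha Significance level for the factor.
#' @param complement Markers entered as `1 - p` (see [build_design()]).
#' @param require_mains Passed to [enumerate_models()].
#' @return An `ooa_scan` list: `models` (per-model label, k, loglik,
#'   AIC, rank), `coefficients` (per-term beta, se, z, raw and corrected
#'   p), `inflation`, `null_pvalues`, `best` (best `gls_fit`).
#' @export
ooa_scan <- function(table, scan_markers = markers(table), R = NULL,
                     max_order = 2, null_generator = NULL, n_null = 10000,
                     seed = NULL, alpha = 0.05, complement = character(),
                     require_mains = TRUE) {
  specs <- enumerate_models(scan_markers, max_order = max_order,
                            require_mains = require_mains)
  fits <- vector("list", length(specs))
  failed <- character()
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      fit_cline_model(table, specs[[i]], R = R, complement = complement),
      error = function(e) { NULL })
    if (is.null(fits[[i]])) failed <- c(failed, format(specs[[i]]))
  }
  ok <- !vapply(fits, is.null, logical(1))
  specs <- specs[ok]; fits <- fits[ok]
  if (length(fits) == 0L) stop("every candidate model failed to fit")

  infl <- NA_real_; nullp <- numeric(0)
  if (!is.null(null_generator)) {
    if (is.null(seed)) stop("a seed is required for the null generator")
    cols <- null_generator(table, n_null, seed)
    nullp <- apply(cols, 2L, function(p) .null_slope_p(table, p, R))
    infl <- inflation_factor(nullp, alpha)
  }

  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  rank_idx <- order(aic, k, seq_along(fits))
  models <- data.frame(
    model = vapply(specs, format, character(1)),
    k = k, loglik = vapply(fits, `[[`, numeric(1), "loglik"), aic = aic,
    rank = match(seq_along(fits), rank_idx))
  coefs <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(model = format(specs[[i]]), term = f$terms,
               beta = unname(f$coefficients), se = unname(f$se),
               z = unname(f$z), p = unname(f$p_value))
  }))
  coefs$p_corrected <- if (is.na(infl)) NA_real_ else
    correct_pvalues(coefs$p, infl)
  structure(list(models = models[order(models$rank), ],
                 coefficients = coefs, inflation = infl,
                 null_pvalues = nullp, best = select_best_aic(fits),
                 failed = failed, alpha = alpha),
            class = "ooa_scan")
}

# univariate slope p-value for one null frequency column
.null_slope_p <- function(table, p, R) {
  x <- arcsine_sqrt(pmin(1, pmax(0, p)))
  X <- cbind(`(Intercept)` = 1, null = x)
  f <- tryCatch(gls_fit(X, table$distance_km, R), error = function(e) NULL)
  if (is.null(f)) NA_real_ else unname(f$p_value[2L])
}

#' @export
print.ooa_scan <- function(x, ...) {
  cat(sprintf("Model scan: %d models fitted; inflation factor %s\n",
              nrow(x$models),
              if (is.na(x$inflation)) "not computed" else
                sprintf("%.3f (%d null fits)", x$inflation,
                        length(x$null_pvalues))))
  print(utils::head(x$models, 5), digits = 6, row.names = FALSE)
  invisible(x)
}
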