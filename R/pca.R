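# Correlation-matrix principal component reduction of demarcation-line
# features, with component selection by cumulative explained variance.

#' Fit a correlation-matrix PCA
#'
#' Standardizes the feature matrix column-wise (Z-scores, n - 1 denominator),
#' forms the correlation matrix `D = Z'Z / (n - 1)` and eigendecomposes it.
#' The number of retained components is the smallest `m` whose cumulative
#' explained variance reaches `variance_target`. Component coefficient
#' vectors are `U_i = P_i / sqrt(lambda_i)` (loadings scaled so the training
#' scores have unit variance); the alternative `P_i / lambda_i` scaling is
#' available via `coefficient_convention = "literal"`. The sign of each
#' component is fixed by forcing its largest-magnitude loading positive.
#'
#' @param features Samples-by-positions data frame or matrix (mm).
#' @param variance_target Cumulative explained-variance fraction used to
#'   select components (default 0.95).
#' @param coefficient_convention `"sqrt"` (default) or `"literal"`; see
#'   Details above.
#' @return An object of class `fishcut_pca` with elements `means`, `sds`,
#'   `eigenvalues` (descending), `loadings` (p x p, orthonormal columns),
#'   `coefficients` (p x n_selected), `n_selected`, `explained` (per-component
#'   variance fractions) and `p`.
#' @export
pca_fit <- function(features, variance_target = 0.95,
                    coefficient_convention = c("sqrt", "literal")) {
  coefficient_convention <- match.arg(coefficient_convention)
  if (variance_target <= 0 || variance_target > 1) {
    stop_invalid("`variance_target` must be in (0, 1].")
  }
  std <- standardize_features(features)
  Z <- std$values
  if (any(!is.finite(Z))) stop_invalid("Feature matrix contains non-finite entries.")
  n <- nrow(Z)
  p <- ncol(Z)
  D <- crossprod(Z) / (n - 1)
  eig <- eigen(D, symmetric = TRUE)
  lambda <- eig$values
  P <- eig$vectors
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(p)) {
    k <- which.max(abs(P[, j]))
    if (P[k, j] < 0) P[, j] <- -P[, j]
  }
  explained <- lambda / sum(lambda)
  m <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  scale_fac <- switch(coefficient_convention,
                      sqrt = sqrt(lambda[seq_len(m)]),
                      literal = lambda[seq_len(m)])
  U <- sweep(P[, seq_len(m), drop = FALSE], 2, scale_fac, "/")
  structure(
    list(means = std$means, sds = std$sds, eigenvalues = lambda,
         loadings = P, coefficients = U, n_selected = m,
         explained = explained, p = p,
         variance_target = variance_target,
         coefficient_convention = coefficient_convention),
    class = "fishcut_pca"
  )
}

#' Project features onto fitted principal components
#'
#' Standardizes `features` with the statistics stored in the model and
#' multiplies by the component coefficient matrix, yielding the
#' principal-component scores used as regression inputs. Training-set scores
#' have zero mean per component.
#'
#' @param model A [pca_fit()] object.
#' @param features Samples-by-positions data frame or matrix with the same
#'   `p` columns the model was fitted on.
#' @return A tibble of scores with columns `pc1 ... pc<m>`.
#' @export
pca_transform <- function(model, features) {
  m <- as.matrix(features)
  if (ncol(m) != model$p) {
    stop_invalid(sprintf("Expected %d feature columns, got %d.", model$p, ncol(m)))
  }
  Z <- sweep(sweep(m, 2, model$means), 2, model$sds, "/")
  scores <- Z %*% model$coefficients
  colnames(scores) <- paste0("pc", seq_len(model$n_selected))
  tibble::as_tibble(scores)
}

#' @export
print.fishcut_pca <- function(x, ...) {
  cat(sprintf("<fishcut_pca> %d features, %d components retained (>= %.0f%% variance)\n",
              x$p, x$n_selected, 100 * x$variance_target))
  cat(sprintf("cumulative variance of retained components: %.3f%%\n",
              100 * sum(x$explained[seq_len(x$n_selected)])))
  invisible(x)
}

#' @describeIn pca_fit Eigenvalue table in broom style: one row per
#'   component with `eigenvalue`, `variance_pct` and `cumulative_pct`.
#' @param x A `fishcut_pca` object.
#' @param ... Unused.
#' @method tidy fishcut_pca
#' @export
tidy.fishcut_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_pct = 100 * x$explained,
    cumulative_pct = 100 * cumsum(x$explained)
  )
}

#' @describeIn pca_fit One-row model summary.
#' @method glance fishcut_pca
#' @export
glance.fishcut_pca <- function(x, ...) {
  tibble::tibble(
    p = x$p,
    n_selected = x$n_selected,
    cumulative_variance = sum(x$explained[seq_len(x$n_selected)]),
    variance_target = x$variance_target
  )
}
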