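# Least-squares support vector machine regression with an RBF kernel.
# Training is one exact solve of the bordered Gram system; hyperparameters
# (gam = regularization, sig2 = kernel width) are tuned by PSO over
# cross-validated RMSE.

#' Gaussian radial basis kernel
#'
#' `k(u, v) = exp(-||u - v||^2 / (2 sig2))`; symmetric, in (0, 1].
#'
#' @param u,v Numeric vectors of equal dimension.
#' @param sig2 Kernel width parameter, > 0.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(u, v, sig2) {
  if (length(u) != length(v)) stop_invalid("`u` and `v` must have equal dimension.")
  check_number(sig2, "sig2", positive = TRUE)
  exp(-sum((u - v)^2) / (2 * sig2))
}

# RBF Gram matrix between row sets A (n x m) and B (k x m).
rbf_gram <- function(A, B, sig2) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sig2))
}

#' Fit an LS-SVM regressor
#'
#' Solves the LS-SVM dual system
#' `[[0, 1'], [1, K + I/gam]] [b; alpha] = [0; y]` exactly, where `K` is the
#' RBF Gram matrix of the training inputs. The first equation forces
#' `sum(alpha) = 0`.
#'
#' @param X Training inputs: data frame or matrix, n x m.
#' @param y Training targets (head lengths, mm), length n.
#' @param gam Regularization parameter, > 0 (larger = less regularization).
#' @param sig2 RBF kernel width, > 0.
#' @return An object of class `fishcut_lssvm` with `support_inputs`,
#'   `alphas`, `bias`, `gam`, `sig2`.
#' @export
lssvm_fit <- function(X, y, gam, sig2) {
  X <- as.matrix(X)
  check_number(gam, "gam", positive = TRUE)
  check_number(sig2, "sig2", positive = TRUE)
  n <- nrow(X)
  if (n < 1L || length(y) != n) stop_invalid("`X` and `y` sizes do not match.")
  K <- rbf_gram(X, X, sig2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gam))
  sol <- tryCatch(solve(A, c(0, y)), error = function(e) {
    rlang::abort(
      sprintf("LS-SVM dual system is singular (rcond %.3e).", rcond(A)),
      class = "fishcut_numerical_error")
  })
  structure(
    list(support_inputs = X, alphas = sol[-1], bias = sol[1],
         gam = gam, sig2 = sig2),
    class = "fishcut_lssvm"
  )
}

#' Predict head lengths from an LS-SVM model
#'
#' Evaluates `f(x) = sum_i alpha_i k(x, x_i) + b` at each query row.
#'
#' @param object A [lssvm_fit()] model.
#' @param newdata Query inputs: data frame or matrix with the training
#'   dimension.
#' @param ... Unused.
#' @return Numeric vector of predictions, mm.
#' @export
predict.fishcut_lssvm <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  if (ncol(Xq) != ncol(object$support_inputs)) {
    stop_invalid("Query dimension does not match the training inputs.")
  }
  drop(rbf_gram(Xq, object$support_inputs, object$sig2) %*% object$alphas) +
    object$bias
}

#' @rdname predict.fishcut_lssvm
#' @param model A [lssvm_fit()] model.
#' @export
lssvm_predict <- function(model, newdata) predict(model, newdata)

# k-fold cross-validated RMSE of an LS-SVM at fixed hyperparameters; folds
# are supplied so the PSO objective is deterministic.
lssvm_cv_rmse <- function(X, y, gam, sig2, folds) {
  err <- purrr::map(unique(folds), function(f) {
    tr <- folds != f
    fit <- lssvm_fit(X[tr, , drop = FALSE], y[tr], gam, sig2)
    predict(fit, X[!tr, , drop = FALSE]) - y[!tr]
  })
  sqrt(mean(unlist(err)^2))
}

#' Tune an LS-SVM by particle swarm search
#'
#' Searches `(sig2, gam)` over `sig2_range` x `gam_range` with PSO,
#' minimizing k-fold cross-validated RMSE (folds fixed by `config$seed`),
#' then refits on all data at the optimum.
#'
#' @inheritParams lssvm_fit
#' @param config A [pso_config()]; defaults to the standard search settings
#'   (swarm 20, 100 iterations, c1 = c2 = 2, inertia 0.9 to 0.3). Velocity
#'   bounds are set to 10% of each parameter range.
#' @param folds Number of cross-validation folds (default 5).
#' @param sig2_range,gam_range Search intervals for the kernel width and the
#'   regularization parameter.
#' @return A `fishcut_lssvm` model with extra elements `cv_rmse` and
#'   `history` (PSO best-fitness trace).
#' @export
tune_lssvm <- function(X, y, config = pso_config(max_iter = 100),
                       folds = 5,
                       sig2_range = c(0.1, 100), gam_range = c(0.01, 100)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop_invalid("Need at least 4 samples for cross-validated tuning.")
  folds <- max(2L, min(as.integer(folds), n))
  fold_id <- withr::with_seed(sub_seed(config$seed, 17),
                              sample(rep_len(seq_len(folds), n)))
  cfg <- config
  cfg$position_bounds <- rbind(c(sig2_range[1], gam_range[1]),
                               c(sig2_range[2], gam_range[2]))
  cfg$velocity_bounds <- rbind(-0.1 * c(diff(sig2_range), diff(gam_range)),
                               0.1 * c(diff(sig2_range), diff(gam_range)))
  obj <- function(pos) lssvm_cv_rmse(X, y, gam = pos[2], sig2 = pos[1], fold_id)
  opt <- pso_optimize(obj, cfg)
  model <- lssvm_fit(X, y, gam = opt$position[2], sig2 = opt$position[1])
  model$cv_rmse <- opt$value
  model$history <- opt$history
  model
}

#' @export
print.fishcut_lssvm <- function(x, ...) {
  cat(sprintf("<fishcut_lssvm> n = %d, gam = %.4g, sig2 = %.4g\n",
              length(x$alphas), x$gam, x$sig2))
  invisible(x)
}

#' Tidy an LS-SVM model
#'
#' @param x A `fishcut_lssvm` model.
#' @param ... Unused.
#' @return A tibble with one row per support point (`alpha` weights).
#' @method tidy fishcut_lssvm
#' @export
tidy.fishcut_lssvm <- function(x, ...) {
  tibble::tibble(observation = seq_along(x$alphas), alpha = x$alphas)
}

#' @rdname tidy.fishcut_lssvm
#' @method glance fishcut_lssvm
#' @export
glance.fishcut_lssvm <- function(x, ...) {
  tibble::tibble(n = length(x$alphas), gam = x$gam, sig2 = x$sig2,
                 bias = x$bias,
                 cv_rmse = if (is.null(x$cv_rmse)) NA_real_ else x$cv_rmse)
}
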