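# Single-hidden-layer back-propagation network (3 inputs, 10 sigmoid hidden
# units, linear output) trained by full-batch gradient descent, optionally
# initialized by particle swarm search over all 51 weights.

#' Construct a back-propagation network
#'
#' A 3-10-1 feed-forward network: sigmoid hidden layer, linear output.
#' Weights are initialized uniformly in \[-0.5, 0.5\] given `seed`, or can be
#' supplied directly.
#'
#' @param n_input,n_hidden Layer sizes (defaults 3 and 10).
#' @param learning_rate Gradient-descent step size (default 0.09).
#' @param max_iter Maximum number of full-batch iterations (default 1000).
#' @param goal Target mean squared error at which training stops
#'   (default 1e-5).
#' @param seed Integer seed for weight initialization.
#' @param weights Optional list with `W1` (n_input x n_hidden), `b1`, `W2`
#'   (n_hidden x 1), `b2` overriding random initialization.
#' @return An object of class `fishcut_bp`.
#' @export
bp_network <- function(n_input = 3, n_hidden = 10, learning_rate = 0.09,
                       max_iter = 1000, goal = 1e-5, seed = 1L,
                       weights = NULL) {
  if (is.null(weights)) {
    weights <- withr::with_seed(seed, list(
      W1 = matrix(runif(n_input * n_hidden, -0.5, 0.5), n_input, n_hidden),
      b1 = runif(n_hidden, -0.5, 0.5),
      W2 = matrix(runif(n_hidden, -0.5, 0.5), n_hidden, 1),
      b2 = runif(1, -0.5, 0.5)
    ))
  }
  structure(
    list(W1 = weights$W1, b1 = weights$b1, W2 = weights$W2, b2 = weights$b2,
         n_input = n_input, n_hidden = n_hidden,
         learning_rate = learning_rate, max_iter = as.integer(max_iter),
         goal = goal),
    class = "fishcut_bp"
  )
}

#' Forward pass of a BP network
#'
#' @param net A [bp_network()].
#' @param X Input matrix or data frame, n x n_input.
#' @return Numeric vector of n predictions.
#' @export
bp_forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$n_input) stop_invalid("Input dimension mismatch.")
  H <- plogis(X %*% net$W1 + rep(net$b1, each = nrow(X)))
  drop(H %*% net$W2) + net$b2
}

#' Analytic gradients of the BP mean squared error
#'
#' Full-batch gradients of `mean((bp_forward(net, X) - y)^2)` with respect to
#' every weight and bias; verified against central finite differences in the
#' test suite.
#'
#' @inheritParams bp_forward
#' @param y Target vector.
#' @return A list with `mse` and gradients `W1`, `b1`, `W2`, `b2`.
#' @export
bp_gradients <- function(net, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  H <- plogis(X %*% net$W1 + rep(net$b1, each = n))
  yhat <- drop(H %*% net$W2) + net$b2
  res <- yhat - y
  d_yhat <- 2 * res / n
  dW2 <- crossprod(H, d_yhat)
  db2 <- sum(d_yhat)
  dH <- tcrossprod(d_yhat, drop(net$W2))
  dZ1 <- dH * H * (1 - H)
  list(mse = mean(res^2),
       W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
       W2 = matrix(dW2, ncol = 1), b2 = db2)
}

#' Train a BP network by full-batch gradient descent
#'
#' Runs at most `net$max_iter` gradient steps with step size
#' `net$learning_rate`, stopping early once the mean squared error reaches
#' `net$goal` (checked before the first update, so a network already at goal
#' is returned unchanged). The parameters with the lowest loss seen are kept,
#' so the returned network is never worse than the initial one.
#'
#' @inheritParams bp_gradients
#' @return The trained network, with `loss_history` (mse before each update
#'   plus final) and `iterations` attached.
#' @export
bp_train <- function(net, X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_invalid("Need at least one training sample.")
  lr <- net$learning_rate
  best <- net[c("W1", "b1", "W2", "b2")]
  g0 <- bp_gradients(net, X, y)
  best_mse <- g0$mse
  history <- numeric(0)
  iterations <- 0L
  g <- g0
  for (it in seq_len(net$max_iter)) {
    history <- c(history, g$mse)
    if (g$mse <= net$goal) break
    net$W1 <- net$W1 - lr * g$W1
    net$b1 <- net$b1 - lr * g$b1
    net$W2 <- net$W2 - lr * g$W2
    net$b2 <- net$b2 - lr * g$b2
    iterations <- it
    g <- bp_gradients(net, X, y)
    if (!is.finite(g$mse)) {
      rlang::abort("BP training diverged (non-finite loss).",
                   class = "fishcut_training_diverged")
    }
    if (g$mse < best_mse) {
      best_mse <- g$mse
      best <- net[c("W1", "b1", "W2", "b2")]
    }
  }
  net[c("W1", "b1", "W2", "b2")] <- best
  net$loss_history <- c(history, best_mse)
  net$mse <- best_mse
  net$iterations <- iterations
  net
}

# Pack / unpack all 51 parameters of a 3-10-1 network (row-major free).
bp_flatten <- function(net) c(net$W1, net$b1, net$W2, net$b2)

bp_unflatten <- function(net, theta) {
  ni <- net$n_input
  nh <- net$n_hidden
  stopifnot(length(theta) == ni * nh + nh + nh + 1)
  net$W1 <- matrix(theta[seq_len(ni * nh)], ni, nh)
  theta <- theta[-seq_len(ni * nh)]
  net$b1 <- theta[seq_len(nh)]
  theta <- theta[-seq_len(nh)]
  net$W2 <- matrix(theta[seq_len(nh)], nh, 1)
  net$b2 <- theta[nh + 1]
  net
}

#' Fit a PSO-initialized BP network
#'
#' Flattens all network parameters into particle positions, runs PSO
#' (positions clipped to \[-2, 2\], velocities to \[-1, 1\] by default) to
#' minimize the training mean squared error, then refines the best particle
#' by gradient descent ([bp_train()]). Inputs and targets are standardized
#' internally (training statistics stored on the model; predictions are
#' mapped back to mm).
#'
#' @param X Training inputs (principal-component scores), n x 3.
#' @param y Training targets (head lengths, mm).
#' @param pso A [pso_config()] (default: swarm 20, 200 iterations).
#' @param net A [bp_network()] template providing sizes and training
#'   settings.
#' @param refine If `FALSE`, skip the gradient-descent refinement and return
#'   the best PSO particle as-is (pure-PSO mode).
#' @return An object of class `fishcut_psobp` with the trained network,
#'   standardization statistics, the PSO fitness `history` and
#'   `pso_best_mse`.
#' @export
pso_bp_fit <- function(X, y, pso = pso_config(), net = bp_network(),
                       refine = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 4L) stop_invalid("Need at least 4 samples.")
  xc <- colMeans(X)
  xs <- apply(X, 2, sd)
  yc <- mean(y)
  ys <- sd(y)
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  ys_t <- (y - yc) / ys
  obj <- function(theta) bp_gradients(bp_unflatten(net, theta), Xs, ys_t)$mse
  npar <- net$n_input * net$n_hidden + 2 * net$n_hidden + 1
  opt <- pso_optimize(obj, pso, d = npar)
  trained <- bp_unflatten(net, opt$position)
  if (refine) trained <- bp_train(trained, Xs, ys_t)
  structure(
    list(net = trained, x_center = xc, x_scale = xs,
         y_center = yc, y_scale = ys,
         history = opt$history, pso_best_mse = opt$value),
    class = "fishcut_psobp"
  )
}

#' @export
predict.fishcut_psobp <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  bp_forward(object$net, Xs) * object$y_scale + object$y_center
}

#' @export
print.fishcut_psobp <- function(x, ...) {
  cat(sprintf("<fishcut_psobp> %d-%d-1 network, PSO best mse %.4g, final mse %.4g\n",
              x$net$n_input, x$net$n_hidden, x$pso_best_mse,
              if (is.null(x$net$mse)) NA else x$net$mse))
  invisible(x)
}

#' Glance at a PSO-BP model
#'
#' @param x A `fishcut_psobp` model.
#' @param ... Unused.
#' @return A one-row tibble of training diagnostics (standardized-scale mse).
#' @method glance fishcut_psobp
#' @export
glance.fishcut_psobp <- function(x, ...) {
  tibble::tibble(n_hidden = x$net$n_hidden,
                 pso_best_mse = x$pso_best_mse,
                 final_mse = if (is.null(x$net$mse)) NA_real_ else x$net$mse,
                 iterations = if (is.null(x$net$iterations)) 0L else x$net$iterations)
}
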