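# Single-layer LSTM regressor built from first principles. The three
# principal-component scores of a fish are consumed as a 3-step univariate
# sequence; the final hidden state maps through a dense layer to the head
# length. Training is full-batch gradient descent on backpropagation-
# through-time gradients with global-norm clipping.

#' Construct an LSTM regression model
#'
#' Standard LSTM cell: sigmoid forget/input/output gates, tanh candidate and
#' hidden activation, zero initial state. Gate weights take the scalar step
#' input (`W*`, length `hidden_size`), recurrent weights the previous hidden
#' state (`V*`, `hidden_size` square); a dense layer (`Wy`, `by`) maps the
#' final hidden state to one output. The forget-gate bias starts at 1.
#'
#' @param hidden_size Number of LSTM units (default 16).
#' @param learning_rate Gradient-descent step size (default 0.005).
#' @param gradient_clip Global-norm gradient threshold (default 1).
#' @param max_iter Maximum number of training epochs (default 200).
#' @param dropout_rate Dropout probability on the hidden-to-output path
#'   during training (default 0.2); never applied at prediction time.
#' @param seed Integer seed for weight initialization and dropout masks.
#' @return An object of class `fishcut_lstm`.
#' @export
lstm_model <- function(hidden_size = 16, learning_rate = 0.005,
                       gradient_clip = 1, max_iter = 200,
                       dropout_rate = 0.2, seed = 1L) {
  H <- as.integer(hidden_size)
  sc <- 1 / sqrt(H)
  w <- withr::with_seed(seed, {
    rv <- function(n) runif(n, -sc, sc)
    list(Wf = rv(H), Wi = rv(H), Wo = rv(H), Wc = rv(H),
         Vf = matrix(rv(H * H), H, H), Vi = matrix(rv(H * H), H, H),
         Vo = matrix(rv(H * H), H, H), Vc = matrix(rv(H * H), H, H),
         bf = rep(1, H), bi = rep(0, H), bo = rep(0, H), bc = rep(0, H),
         Wy = rv(H), by = 0)
  })
  structure(
    list(weights = w, hidden_size = H, learning_rate = learning_rate,
         gradient_clip = gradient_clip, max_iter = as.integer(max_iter),
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "fishcut_lstm"
  )
}

# Forward pass storing per-step activations for BPTT. `mask` is an inverted
# dropout multiplier on the final hidden state (NULL = identity).
lstm_forward_full <- function(model, X, mask = NULL) {
  w <- model$weights
  H <- model$hidden_size
  X <- as.matrix(X)
  n <- nrow(X)
  steps <- ncol(X)
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  cache <- vector("list", steps)
  for (t in seq_len(steps)) {
    xt <- X[, t]
    f <- plogis(outer(xt, w$Wf) + h %*% w$Vf + rep(w$bf, each = n))
    i <- plogis(outer(xt, w$Wi) + h %*% w$Vi + rep(w$bi, each = n))
    o <- plogis(outer(xt, w$Wo) + h %*% w$Vo + rep(w$bo, each = n))
    g <- tanh(outer(xt, w$Wc) + h %*% w$Vc + rep(w$bc, each = n))
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                       f = f, i = i, o = o, g = g, c = c_new)
    h <- h_new
    cc <- c_new
  }
  hm <- if (is.null(mask)) h else sweep(h, 2, mask, "*")
  yhat <- drop(hm %*% w$Wy) + w$by
  list(yhat = yhat, h_final = h, cache = cache, mask = mask)
}

#' LSTM forward pass
#'
#' Feeds each row of `X` as a 3-step univariate sequence through the LSTM
#' cell recurrences and returns the dense-layer output. No dropout is
#' applied.
#'
#' @param model A [lstm_model()].
#' @param X Input matrix or data frame (n x 3), or a single 3-vector.
#' @return Numeric vector of predictions.
#' @export
lstm_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (any(!vapply(model$weights, function(w) all(is.finite(w)), logical(1)))) {
    rlang::abort("LSTM model has non-finite parameters.",
                 class = "fishcut_invalid_state")
  }
  lstm_forward_full(model, X)$yhat
}

#' Backpropagation-through-time gradients of the LSTM mean squared error
#'
#' Full-batch analytic gradients of `mean((lstm_forward(model, X) - y)^2)`
#' with respect to every weight; verified against central finite differences
#' in the test suite. An optional dropout `mask` (inverted-dropout
#' multipliers on the final hidden state) is differentiated through.
#'
#' @inheritParams lstm_forward
#' @param y Target vector.
#' @param mask Optional length-`hidden_size` dropout multiplier.
#' @return A list with `mse` and a `grads` list matching `model$weights`.
#' @export
lstm_gradients <- function(model, X, y, mask = NULL) {
  w <- model$weights
  H <- model$hidden_size
  X <- as.matrix(X)
  n <- nrow(X)
  fw <- lstm_forward_full(model, X, mask)
  res <- fw$yhat - y
  d_yhat <- 2 * res / n
  hm <- if (is.null(mask)) fw$h_final else sweep(fw$h_final, 2, mask, "*")
  gr <- list(Wf = numeric(H), Wi = numeric(H), Wo = numeric(H), Wc = numeric(H),
             Vf = matrix(0, H, H), Vi = matrix(0, H, H),
             Vo = matrix(0, H, H), Vc = matrix(0, H, H),
             bf = numeric(H), bi = numeric(H), bo = numeric(H), bc = numeric(H),
             Wy = drop(crossprod(hm, d_yhat)), by = sum(d_yhat))
  dh <- outer(d_yhat, if (is.null(mask)) w$Wy else w$Wy * mask)
  dc <- matrix(0, n, H)
  for (t in rev(seq_along(fw$cache))) {
    st <- fw$cache[[t]]
    tc <- tanh(st$c)
    do <- dh * tc
    dc <- dc + dh * st$o * (1 - tc^2)
    dZo <- do * st$o * (1 - st$o)
    dg <- dc * st$i
    dZg <- dg * (1 - st$g^2)
    di <- dc * st$g
    dZi <- di * st$i * (1 - st$i)
    df <- dc * st$c_prev
    dZf <- df * st$f * (1 - st$f)
    gr$Wf <- gr$Wf + drop(crossprod(dZf, st$xt))
    gr$Wi <- gr$Wi + drop(crossprod(dZi, st$xt))
    gr$Wo <- gr$Wo + drop(crossprod(dZo, st$xt))
    gr$Wc <- gr$Wc + drop(crossprod(dZg, st$xt))
    gr$Vf <- gr$Vf + crossprod(st$h_prev, dZf)
    gr$Vi <- gr$Vi + crossprod(st$h_prev, dZi)
    gr$Vo <- gr$Vo + crossprod(st$h_prev, dZo)
    gr$Vc <- gr$Vc + crossprod(st$h_prev, dZg)
    gr$bf <- gr$bf + colSums(dZf)
    gr$bi <- gr$bi + colSums(dZi)
    gr$bo <- gr$bo + colSums(dZo)
    gr$bc <- gr$bc + colSums(dZg)
    dh <- dZf %*% t(w$Vf) + dZi %*% t(w$Vi) +
      dZo %*% t(w$Vo) + dZg %*% t(w$Vc)
    dc <- dc * st$f
  }
  list(mse = mean(res^2), grads = gr)
}

# Pack / unpack all LSTM parameters as one vector (finite-difference checks,
# global-norm computation).
lstm_flatten <- function(model) unlist(model$weights, use.names = FALSE)

lstm_unflatten <- function(model, theta) {
  shapes <- model$weights
  pos <- 0L
  for (nm in names(shapes)) {
    len <- length(shapes[[nm]])
    val <- theta[pos + seq_len(len)]
    if (is.matrix(shapes[[nm]])) {
      model$weights[[nm]] <- matrix(val, nrow(shapes[[nm]]), ncol(shapes[[nm]]))
    } else if (len == 1L) {
      model$weights[[nm]] <- val
    } else {
      model$weights[[nm]] <- val
    }
    pos <- pos + len
  }
  model
}

#' Train an LSTM head-length regressor
#'
#' Full-batch training on backpropagation-through-time gradients: the
#' global gradient norm is clipped at `gradient_clip`, then parameters are
#' updated with Adam-style adaptive steps (moment decays 0.9 / 0.999)
#' starting from the initial learning rate, for at most `max_iter` epochs.
#' Inverted dropout (one mask per epoch, rate `dropout_rate`) is applied to
#' the hidden-to-output path during training only. Inputs and targets are
#' standardized internally (statistics stored; predictions return in mm).
#' Training and (optional) validation loss histories are computed without
#' dropout.
#'
#' @param X Training inputs (principal-component scores), n x 3.
#' @param y Training targets (head lengths, mm).
#' @param model A [lstm_model()] template.
#' @param validation Optional list `list(X =, y =)` whose loss is tracked
#'   per epoch.
#' @return An object of class `fishcut_lstm_fit` with the trained model,
#'   standardization statistics and `loss_history` /
#'   `validation_history` (standardized scale).
#' @export
lstm_fit <- function(X, y, model = lstm_model(), validation = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 4L) stop_invalid("Need at least 4 samples.")
  xc <- colMeans(X)
  xs <- apply(X, 2, sd)
  yc <- mean(y)
  ysd <- sd(y)
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  ys <- (y - yc) / ysd
  H <- model$hidden_size
  keep <- 1 - model$dropout_rate
  masks <- withr::with_seed(sub_seed(model$seed, 101), {
    matrix(rbinom(model$max_iter * H, 1, keep), model$max_iter, H) / keep
  })
  if (model$dropout_rate == 0) masks[] <- 1
  vXs <- NULL
  if (!is.null(validation)) {
    vXs <- sweep(sweep(as.matrix(validation$X), 2, xc), 2, xs, "/")
    vys <- (validation$y - yc) / ysd
  }
  loss_hist <- numeric(model$max_iter)
  val_hist <- numeric(model$max_iter)
  m1 <- 0
  m2 <- 0
  b1 <- 0.9
  b2 <- 0.999
  for (epoch in seq_len(model$max_iter)) {
    gstep <- lstm_gradients(model, Xs, ys, mask = masks[epoch, ])
    if (!is.finite(gstep$mse)) {
      rlang::abort("LSTM training diverged (non-finite loss).",
                   class = "fishcut_training_diverged")
    }
    gvec <- unlist(gstep$grads, use.names = FALSE)
    gnorm <- sqrt(sum(gvec^2))
    if (gnorm > model$gradient_clip) gvec <- gvec * model$gradient_clip / gnorm
    m1 <- b1 * m1 + (1 - b1) * gvec
    m2 <- b2 * m2 + (1 - b2) * gvec^2
    step <- model$learning_rate * (m1 / (1 - b1^epoch)) /
      (sqrt(m2 / (1 - b2^epoch)) + 1e-8)
    model <- lstm_unflatten(model, lstm_flatten(model) - step)
    loss_hist[epoch] <- mean((lstm_forward_full(model, Xs)$yhat - ys)^2)
    if (!is.null(vXs)) {
      val_hist[epoch] <- mean((lstm_forward_full(model, vXs)$yhat - vys)^2)
    }
  }
  structure(
    list(model = model, x_center = xc, x_scale = xs,
         y_center = yc, y_scale = ysd,
         loss_history = loss_hist,
         validation_history = if (is.null(vXs)) NULL else val_hist),
    class = "fishcut_lstm_fit"
  )
}

#' @export
predict.fishcut_lstm_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  lstm_forward(object$model, Xs) * object$y_scale + object$y_center
}

#' @export
print.fishcut_lstm_fit <- function(x, ...) {
  cat(sprintf("<fishcut_lstm_fit> %d units, %d epochs, final training mse %.4g (standardized)\n",
              x$model$hidden_size, x$model$max_iter,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Glance at a fitted LSTM
#'
#' @param x A `fishcut_lstm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble of training diagnostics (standardized scale).
#' @method glance fishcut_lstm_fit
#' @export
glance.fishcut_lstm_fit <- function(x, ...) {
  tibble::tibble(hidden_size = x$model$hidden_size,
                 epochs = x$model$max_iter,
                 final_loss = x$loss_history[length(x$loss_history)],
                 dropout_rate = x$model$dropout_rate)
}
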