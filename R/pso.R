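# Canonical particle swarm optimization with linearly decaying inertia,
# used both for LS-SVM hyperparameter search and BP weight initialization.

#' Particle swarm configuration
#'
#' @param swarm_size Number of particles (default 20).
#' @param max_iter Number of iterations.
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2).
#' @param inertia_max,inertia_min Inertia weight, decayed linearly from
#'   `inertia_max` to `inertia_min` over `max_iter` (defaults 0.9 and 0.3).
#' @param position_bounds 2 x d matrix (rows: lower, upper) or length-2
#'   vector recycled to all dimensions.
#' @param velocity_bounds Same shape as `position_bounds`; velocities are
#'   clipped to this box.
#' @param seed Integer seed.
#' @return A list of class `fishcut_pso_config`.
#' @export
pso_config <- function(swarm_size = 20, max_iter = 200, c1 = 2, c2 = 2,
                       inertia_max = 0.9, inertia_min = 0.3,
                       position_bounds = c(-2, 2),
                       velocity_bounds = c(-1, 1),
                       seed = 1L) {
  if (swarm_size < 2) stop_invalid("`swarm_size` must be >= 2.")
  if (inertia_min <= 0 || inertia_max < inertia_min) {
    stop_invalid("Need inertia_max >= inertia_min > 0.")
  }
  structure(
    list(swarm_size = as.integer(swarm_size), max_iter = as.integer(max_iter),
         c1 = c1, c2 = c2, inertia_max = inertia_max,
         inertia_min = inertia_min, position_bounds = position_bounds,
         velocity_bounds = velocity_bounds, seed = as.integer(seed)),
    class = "fishcut_pso_config"
  )
}

as_bounds <- function(b, d) {
  if (is.matrix(b)) {
    if (ncol(b) == 1L) b <- b[, rep(1L, d), drop = FALSE]
    if (ncol(b) != d) stop_invalid("Bounds dimension mismatch.")
  } else {
    b <- matrix(rep(b, d), nrow = 2)
  }
  if (any(b[1, ] >= b[2, ])) stop_invalid("Bounds must be non-empty intervals.")
  b
}

#' Particle swarm optimization
#'
#' Minimizes `objective` over the position box: velocities follow
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with the inertia `w`
#' decayed linearly, and both velocities and positions are clipped to their
#' boxes. Deterministic given `config$seed`.
#'
#' @param objective Function of a position vector returning a finite scalar.
#' @param config A [pso_config()]; dimensionality is taken from
#'   `config$position_bounds` (or `d`).
#' @param d Number of dimensions if `position_bounds` is a length-2 vector.
#' @return A list with `position` (best found), `value`, and `history` (best
#'   value after each iteration, non-increasing).
#' @export
pso_optimize <- function(objective, config = pso_config(), d = NULL) {
  pb <- config$position_bounds
  if (is.null(d)) d <- if (is.matrix(pb)) ncol(pb) else 2L
  pb <- as_bounds(pb, d)
  vb <- as_bounds(config$velocity_bounds, d)
  ns <- config$swarm_size
  withr::with_seed(config$seed, {
    X <- matrix(runif(ns * d, pb[1, ], pb[2, ]), nrow = d)
    V <- matrix(runif(ns * d, vb[1, ], vb[2, ]), nrow = d)
    fit <- apply(X, 2, objective)
    if (any(!is.finite(fit))) stop_invalid("Objective returned a non-finite value.")
    pbest_x <- X
    pbest_f <- fit
    g <- which.min(fit)
    gbest_x <- X[, g]
    gbest_f <- fit[g]
    history <- numeric(config$max_iter)
    for (it in seq_len(config$max_iter)) {
      w <- config$inertia_max -
        (config$inertia_max - config$inertia_min) * (it - 1) / max(1, config$max_iter - 1)
      r1 <- matrix(runif(ns * d), nrow = d)
      r2 <- matrix(runif(ns * d), nrow = d)
      V <- w * V + config$c1 * r1 * (pbest_x - X) +
        config$c2 * r2 * (gbest_x - X)
      V <- pmin(pmax(V, vb[1, ]), vb[2, ])
      X <- pmin(pmax(X + V, pb[1, ]), pb[2, ])
      fit <- apply(X, 2, objective)
      improved <- fit < pbest_f
      pbest_x[, improved] <- X[, improved]
      pbest_f[improved] <- fit[improved]
      g <- which.min(pbest_f)
      if (pbest_f[g] < gbest_f) {
        gbest_f <- pbest_f[g]
        gbest_x <- pbest_x[, g]
      }
      history[it] <- gbest_f
    }
  })
  list(position = gbest_x, value = gbest_f, history = history)
}
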