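# Independent reference implementations used as oracles. These deliberately
# use the most literal, brute-force formulation of each operation and share
# no code with the package internals.

# Adjacent-difference segmentation by explicit scan: walk every adjacent
# pair, record those whose absolute height jump exceeds the threshold, and
# carve the fish region between the first and the last such jump.
oracle_segment <- function(z, threshold) {
  jumps <- integer(0)
  for (i in seq_len(length(z) - 1)) {
    if (abs(z[i + 1] - z[i]) > threshold) jumps <- c(jumps, i)
  }
  if (length(jumps) == 0 || min(jumps) == max(jumps)) {
    return(list(fish = integer(0), left = seq_along(z), right = integer(0)))
  }
  i1 <- min(jumps)
  i2 <- max(jumps)
  list(fish = (i1 + 1):i2,
       left = 1:i1,
       right = if (i2 < length(z)) (i2 + 1):length(z) else integer(0))
}

# Sliding median by explicit sort-and-middle of each (truncated) window.
oracle_median_filter <- function(z, left, right) {
  n <- length(z)
  out <- numeric(n)
  for (k in seq_len(n)) {
    w <- sort(z[max(1, k - left):min(n, k + right)])
    m <- length(w)
    out[k] <- if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

# Scalar Riccati fixed point of the constant-position Kalman recursion:
# iterate the covariance update until it stops moving, then report the gain.
oracle_steady_gain <- function(q, r, p0 = 1, tol = 1e-14, max_iter = 1e6) {
  p <- p0
  gain <- NA_real_
  for (i in seq_len(max_iter)) {
    pp <- p + q
    g <- pp / (pp + r)
    p_new <- (1 - g) * pp
    if (!is.na(gain) && abs(g - gain) < tol) return(g)
    gain <- g
    p <- p_new
  }
  gain
}

# Symmetric eigendecomposition by power iteration with deflation; returns
# eigenvalues (descending) and unit eigenvectors. Slow and simple.
oracle_eigen_sym <- function(A, tol = 1e-13, max_iter = 50000) {
  p <- ncol(A)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  # shift to make all eigenvalues positive so power iteration targets the
  # largest remaining one
  shift <- sum(abs(A)) + 1
  B <- A + shift * diag(p)
  for (j in seq_len(p)) {
    v <- rep(1 / sqrt(p), p)
    lam_old <- Inf
    for (it in seq_len(max_iter)) {
      w <- B %*% v
      if (j > 1) {
        for (k in seq_len(j - 1)) {
          w <- w - vecs[, k] * sum(vecs[, k] * w)
        }
      }
      nv <- sqrt(sum(w^2))
      v <- as.vector(w) / nv
      lam <- sum(v * (B %*% v))
      if (abs(lam - lam_old) < tol) break
      lam_old <- lam
    }
    vals[j] <- lam - shift
    vecs[, j] <- v
  }
  list(values = vals, vectors = vecs)
}

# Dense linear solve by textbook Gaussian elimination with partial pivoting.
oracle_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    for (i in (k + 1):n) {
      f <- M[i, k] / M[k, k]
      M[i, ] <- M[i, ] - f * M[k, ]
    }
  }
  x <- numeric(n)
  for (i in n:1) {
    x[i] <- (M[i, n + 1] - sum(M[i, seq_len(n)] * x)) / M[i, i]
  }
  x
}

# Central finite-difference gradient of f at theta.
oracle_fd_gradient <- function(f, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta
    tm <- theta
    tp[i] <- tp[i] + eps
    tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

# Piecewise-linear interpolation at a single point by explicit bracket
# search.
oracle_interp <- function(x, y, x0) {
  if (x0 <= x[1]) return(y[1])
  n <- length(x)
  if (x0 >= x[n]) return(y[n])
  i <- max(which(x <= x0))
  if (x[i] == x0) return(y[i])
  y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
}
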