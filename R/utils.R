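# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index,
# so independent stages never share a random stream.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + k * 100003) %% 2147483629)
}

stop_invalid <- function(msg, class = "fishcut_invalid_argument") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) stop_invalid(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) stop_invalid(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_cloud <- function(cloud, name = "cloud") {
  if (!is.data.frame(cloud) || !all(c("x", "y", "z") %in% names(cloud))) {
    stop_invalid(sprintf("`%s` must be a data frame with columns x, y, z.", name))
  }
  if (nrow(cloud) == 0L) stop_invalid(sprintf("`%s` is empty.", name))
  invisible(cloud)
}

# Inverse-CDF sampler for a truncated normal; `u` are Uniform(0,1) draws.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  qnorm(plo + u * (phi - plo)) * sd + mean
}

# Mean of a truncated normal (used by tests as a closed-form reference too).
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
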