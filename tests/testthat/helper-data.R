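# Small in-code fixtures shared by several test files.

# A reduced-resolution scan configuration that keeps unit tests fast while
# preserving the geometry (laser wider than the fish, belt margins).
test_scan_config <- function(...) {
  args <- utils::modifyList(list(points_per_line = 240, frame_spacing = 4),
                            list(...))
  do.call(scan_config, args)
}

noiseless_config <- function(...) {
  args <- utils::modifyList(list(gaussian_noise_sd = 0, impulse_rate = 0,
                                 vibration_amplitude = 0), list(...))
  do.call(test_scan_config, args)
}

one_fish <- function(seed = 42) sample_fish_params(1, seed = seed)

# PC-score-like regression fixture: 3 informative-ish inputs and a smooth
# target map with mild noise.
score_fixture <- function(n, seed = 1, noise_sd = 0.2) {
  withr::with_seed(seed, {
    X <- cbind(rnorm(n), rnorm(n), rnorm(n))
    y <- 55 + 2.2 * X[, 1] - 0.6 * X[, 2] + 0.3 * tanh(X[, 3]) +
      rnorm(n, sd = noise_sd)
  })
  list(X = X, y = y)
}
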