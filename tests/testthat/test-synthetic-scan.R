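test_that("sampled shape parameters respect population bounds and are reproducible", {
  p <- sample_fish_params(204, seed = 1)
  expect_equal(nrow(p), 204)
  expect_true(all(p$head_length >= 50.1 & p$head_length <= 63.1))
  expect_true(all(p$total_length >= 200.8 & p$total_length <= 239.4))
  expect_true(all(p$max_width >= 94.6 & p$max_width <= 103.7))
  expect_true(all(p$max_thickness >= 45.3 & p$max_thickness <= 51.54))
  expect_true(all(p$head_length < p$total_length))
  expect_true(all(p$thickness_peak_frac > 0 & p$thickness_peak_frac < 1))
  expect_true(all(p$cross_section_exponent > 0))
  expect_identical(p, sample_fish_params(204, seed = 1))
  expect_identical(sample_fish_params(1, seed = 7), sample_fish_params(1, seed = 7))
  # allometry: larger fish have longer heads
  expect_gt(cor(p$head_length, p$total_length), 0.5)
  expect_gt(cor(p$head_length, p$max_thickness), 0.9)
  expect_error(sample_fish_params(0, seed = 1), class = "fishcut_invalid_argument")
})

test_that("truncated-normal thickness marginal matches a Monte-Carlo oracle", {
  p <- sample_fish_params(1000, seed = 3)
  # oracle: large-sample rejection estimate of the truncated-normal mean
  draws <- withr::with_seed(99, rnorm(4e5, 47.49, 1.85))
  draws <- draws[draws >= 45.3 & draws <= 51.54]
  se <- sd(p$max_thickness) / sqrt(1000)
  expect_lt(abs(mean(p$max_thickness) - mean(draws)), 3 * se)
})

test_that("analytic surface: footprint, envelope peak, symmetry and lateral maximum", {
  params <- one_fish()
  L <- params$total_length
  expect_identical(fish_height(params, c(-1, L + 1e-9, 2 * L), 0), c(0, 0, 0))
  # envelope peak value and location by construction
  xp <- params$thickness_peak_frac * L
  expect_equal(fish_height(params, xp, 0), params$max_thickness)
  expect_equal(fish_envelope(params, xp), params$max_thickness)
  # brute-force lateral grid maximization attains the midline value
  for (x in c(0.2, 0.45, 0.8) * L) {
    grid <- seq(-params$max_width, params$max_width, length.out = 4001)
    expect_equal(max(fish_height(params, x, grid)), fish_height(params, x, 0),
                 tolerance = 1e-6)
    ys <- seq(0.1, 60, by = 3.7)
    expect_equal(fish_height(params, rep(x, length(ys)), ys),
                 fish_height(params, rep(x, length(ys)), -ys))
  }
  # envelope is unimodal around its peak
  xs <- seq(1e-6, L - 1e-6, length.out = 400)
  env <- fish_envelope(params, xs)
  expect_equal(which.max(env), which.min(abs(xs - xp)), tolerance = 2)
})

test_that("noiseless scans put belt points exactly at the belt plane and the ridge on the envelope", {
  params <- one_fish()
  cfg <- noiseless_config(belt_height = 250.32)
  cloud <- simulate_scan(params, cfg)
  truth <- fish_height(params, cloud$x - cfg$belt_margin, cloud$y)
  expect_identical(unique(cloud$z[truth == 0]), 250.32)
  # per-frame maximum equals the envelope within the lateral grid resolution
  ridge <- cloud |>
    dplyr::group_by(x) |>
    dplyr::summarise(h = max(z) - cfg$belt_height)
  env <- fish_envelope(params, ridge$x - cfg$belt_margin)
  # brute-force check on a fine grid for a few frames
  for (k in c(10, 25, 40)) {
    fine <- max(fish_height(params, ridge$x[k] - cfg$belt_margin,
                            seq(-80, 80, length.out = 20001)))
    expect_equal(ridge$h[k], fine, tolerance = 1e-4)
  }
  expect_true(all(abs(ridge$h - env) < 0.01))
})

test_that("scans and datasets are bit-identical under a fixed seed", {
  params <- one_fish()
  cfg <- test_scan_config(seed = 5L)
  expect_identical(simulate_scan(params, cfg), simulate_scan(params, cfg))
  expect_identical(generate_dataset(2, test_scan_config(), seed = 5),
                   generate_dataset(2, test_scan_config(), seed = 5))
  wide <- sample_fish_params(1, seed = 1)
  wide$max_width <- 200
  expect_error(simulate_scan(wide, cfg), class = "fishcut_invalid_argument")
})

test_that("gaussian noise level monotonically increases deviation from the noiseless scan", {
  params <- one_fish()
  base <- noiseless_config(frame_spacing = 2)
  clean <- simulate_scan(params, base)
  msd <- vapply(c(0.1, 0.3, 0.6), function(s) {
    cfg <- noiseless_config(frame_spacing = 2, gaussian_noise_sd = s, seed = 8L)
    mean((simulate_scan(params, cfg)$z - clean$z)^2)
  }, numeric(1))
  expect_gt(length(unique(clean$x)), 100)
  expect_true(all(diff(msd) > 0))
})

test_that("noiseless fish point count matches the analytic footprint area", {
  params <- one_fish()
  cfg <- noiseless_config()
  cloud <- simulate_scan(params, cfg)
  n_fish_pts <- sum(cloud$z > cfg$belt_height + 1e-9)
  # plan-view footprint: elliptical outline of half-width w(x)
  area <- integrate(function(x) 2 * fishcut:::fish_halfwidth(params, x),
                    0, params$total_length, rel.tol = 1e-10)$value
  cell <- (cfg$lateral_span / (cfg$points_per_line - 1)) * cfg$frame_spacing
  expect_lt(abs(n_fish_pts - area / cell) / (area / cell), 0.05)
})

test_that("generated datasets carry ground truth consistently", {
  cfg <- noiseless_config()
  ds <- generate_dataset(12, cfg, seed = 4)
  expect_length(ds$clouds, 12)
  expect_identical(ds$head_lengths, ds$params$head_length)
  expect_true(all(ds$head_lengths > 0))
  # demarcation maximum sits at the thickness peak within one frame spacing
  for (i in c(2, 7, 11)) {
    line <- extract_demarcation_line(preprocess_cloud(ds$clouds[[i]]),
                                     belt_height = cfg$belt_height)
    x_peak <- line$x[which.max(line$h)] - cfg$belt_margin
    x_true <- ds$params$thickness_peak_frac[i] * ds$params$total_length[i]
    expect_lt(abs(x_peak - x_true), cfg$frame_spacing + 1e-9)
  }
})
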