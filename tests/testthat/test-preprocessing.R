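test_that("threshold segmentation matches a brute-force adjacent-difference scan", {
  withr::with_seed(10, {
    for (rep in 1:300) {
      n <- sample(2:40, 1)
      # mix of flat belts, plateaus and jumpy frames
      z <- round(cumsum(sample(c(0, 0, 1, -1, 8, -8), n, replace = TRUE)) +
                   rnorm(n, sd = 0.3), 2)
      threshold <- sample(c(0.5, 2, 5), 1)
      frame <- tibble::tibble(y = seq_len(n), z = z)
      got <- threshold_segment(frame, threshold)
      want <- oracle_segment(z, threshold)
      expect_identical(got$fish$y, as.integer(want$fish))
      expect_identical(got$left_belt$y, as.integer(want$left))
      expect_identical(got$right_belt$y, as.integer(want$right))
      # partition: concatenation restores the frame
      expect_identical(
        dplyr::bind_rows(got$left_belt, got$fish, got$right_belt), frame)
    }
  })
})

test_that("segmentation handles flat belts, the worked example, and oversized thresholds", {
  flat <- tibble::tibble(y = 1:10, z = rep(250.32, 10))
  seg <- threshold_segment(flat, 5)
  expect_identical(nrow(seg$fish), 0L)
  expect_identical(nrow(seg$left_belt) + nrow(seg$right_belt), 10L)
  expect_identical(seg$threshold_used, 5)

  frame <- tibble::tibble(y = 1:8, z = c(0, 0, 0, 10, 12, 10, 0, 0))
  seg <- threshold_segment(frame, 5)
  expect_identical(seg$fish$y, 4:6)
  expect_identical(seg$left_belt$y, 1:3)
  expect_identical(seg$right_belt$y, 7:8)

  # threshold above the global range: nothing can jump over it
  expect_identical(nrow(threshold_segment(frame, 50)$fish), 0L)
  expect_error(threshold_segment(frame[0, ], 5), class = "fishcut_invalid_argument")
  expect_error(threshold_segment(frame, -1), class = "fishcut_invalid_argument")
})

test_that("kalman filter: constant invariance, Riccati steady state, noise suppression", {
  expect_identical(kalman_filter(rep(3.7, 50)), rep(3.7, 50))
  expect_error(kalman_filter(numeric(0)), class = "fishcut_invalid_argument")

  q <- 1e-4
  r <- 0.1
  gains <- kalman_gains(5000)
  # closed-form scalar Riccati fixed point
  p_inf <- (-q + sqrt(q^2 + 4 * q * r)) / 2
  k_inf <- (p_inf + q) / (p_inf + q + r)
  expect_lt(abs(gains[5000] - k_inf), 1e-12)
  # iterative covariance-recursion oracle agrees
  expect_lt(abs(oracle_steady_gain(q, r) - k_inf), 1e-12)

  z <- withr::with_seed(21, rnorm(10000))
  out <- kalman_filter(z)
  expect_length(out, 10000)
  expect_lt(var(out), 0.2 * var(z))
})

test_that("median filter equals sort-and-middle, removes spikes, preserves range", {
  withr::with_seed(11, {
    for (rep in 1:60) {
      n <- sample(1:40, 1)
      z <- rnorm(n)
      left <- sample(0:3, 1)
      right <- sample(0:3, 1)
      if (left + right == 0) left <- 2
      cfg <- filter_config(median_window_left = left, median_window_right = right)
      got <- median_filter(z, cfg)
      expect_equal(got, oracle_median_filter(z, left, right))
      expect_true(all(got >= min(z) & got <= max(z)))
    }
  })
  # symmetric 3-point window wipes an isolated spike
  sym <- filter_config(median_window_left = 1, median_window_right = 1)
  expect_identical(median_filter(c(0, 0, 100, 0, 0), sym), rep(0, 5))
  # constants are fixed points
  expect_identical(median_filter(rep(2.5, 9)), rep(2.5, 9))
  expect_error(median_filter(numeric(0)), class = "fishcut_invalid_argument")
})

test_that("profile pipeline applies Kalman then median, in that order", {
  withr::with_seed(12, z <- c(rep(0.2, 3), 18 + rnorm(20), rep(0.1, 3)))
  frame <- tibble::tibble(x = 1, y = seq_along(z), z = z)
  out <- preprocess_cloud(frame, threshold = 5)
  fish_z <- z[threshold_segment(frame, 5)$fish$y]
  expect_equal(out$z, median_filter(kalman_filter(fish_z)))
  # the reversed composition differs on this frame
  expect_false(isTRUE(all.equal(out$z, kalman_filter(median_filter(fish_z)))))
})

test_that("frame retention on noiseless clouds matches an oracle re-derivation", {
  params <- one_fish(7)
  cfg <- noiseless_config()
  cloud <- simulate_scan(params, cfg)
  out <- preprocess_cloud(cloud, 5)
  expected <- Filter(Negate(is.null), lapply(split(cloud, cloud$x), function(fr) {
    sg <- oracle_segment(fr$z, 5)
    if (length(sg$fish) == 0) return(NULL)
    zf <- oracle_median_filter(kalman_filter(fr$z[sg$fish]), 2, 1)
    belt <- median(fr$z[c(sg$left, sg$right)])
    if (max(zf) - belt <= 5) return(NULL)
    fr$x[1]
  }))
  expect_identical(unique(out$x), unname(unlist(expected)))
  # all-belt cloud yields a diagnostic error
  flat <- tibble::tibble(x = rep(1:3, each = 5), y = rep(1:5, 3), z = 250.32)
  expect_error(preprocess_cloud(flat, 5), class = "fishcut_empty_result")
})

test_that("filtering suppresses white noise on flat profiles and cleans the demarcation line", {
  # flat signal + noise: strong variance reduction
  withr::with_seed(13, {
    truth <- rep(40, 2000)
    z <- truth + rnorm(2000, sd = 0.3)
  })
  zf <- median_filter(kalman_filter(z))
  expect_lt(sqrt(mean((zf - truth)^2)), 0.6 * sqrt(mean((z - truth)^2)))

  # line level: filtered per-frame maxima track the envelope far better than
  # raw maxima (impulse outliers corrupt the raw line)
  params <- one_fish(3)
  cfg <- test_scan_config(seed = 31L)
  cloud <- simulate_scan(params, cfg)
  raw_fish <- dplyr::bind_rows(lapply(split(cloud, cloud$x), function(fr) {
    threshold_segment(fr, 5)$fish
  }))
  line_raw <- extract_demarcation_line(raw_fish, cfg$belt_height)
  line_fil <- extract_demarcation_line(preprocess_cloud(cloud, 5), cfg$belt_height)
  rmse_line <- function(l) {
    sqrt(mean((l$h - fish_envelope(params, l$x - cfg$belt_margin))^2))
  }
  expect_lt(rmse_line(line_fil), 0.6 * rmse_line(line_raw))
})
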