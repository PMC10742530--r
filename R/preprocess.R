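# Raw-frame preprocessing: threshold segmentation of belt vs fish points and
# Kalman + median denoising of each radial profile.

#' Filter configuration for profile denoising
#'
#' @param kalman_process_cov Process (system) noise covariance of the scalar
#'   Kalman recursion, mm^2.
#' @param kalman_measurement_cov Measurement noise covariance, mm^2.
#' @param kalman_initial_cov Initial state covariance, mm^2.
#' @param median_window_left,median_window_right Number of points the sliding
#'   median window extends to the left/right of the current index; the
#'   default `[-2, +1]` window covers 4 points. Windows are truncated at the
#'   profile edges.
#' @return A list of class `fishcut_filter_config`.
#' @export
filter_config <- function(kalman_process_cov = 1e-4,
                          kalman_measurement_cov = 0.1,
                          kalman_initial_cov = 1,
                          median_window_left = 2L,
                          median_window_right = 1L) {
  check_number(kalman_process_cov, "kalman_process_cov", positive = TRUE)
  check_number(kalman_measurement_cov, "kalman_measurement_cov", positive = TRUE)
  check_number(kalman_initial_cov, "kalman_initial_cov", positive = TRUE)
  check_number(median_window_left, "median_window_left", nonneg = TRUE)
  check_number(median_window_right, "median_window_right", nonneg = TRUE)
  if (median_window_left + median_window_right < 1) {
    stop_invalid("The median window must cover at least 2 points.")
  }
  structure(
    list(kalman_process_cov = kalman_process_cov,
         kalman_measurement_cov = kalman_measurement_cov,
         kalman_initial_cov = kalman_initial_cov,
         median_window_left = as.integer(median_window_left),
         median_window_right = as.integer(median_window_right)),
    class = "fishcut_filter_config"
  )
}

#' Threshold segmentation of a radial profile
#'
#' Splits one laser frame into left belt, fish body and right belt regions by
#' scanning the absolute height differences of laterally adjacent points. The
#' fish region is the maximal contiguous run bounded on the left by the first
#' adjacent-pair jump exceeding `threshold` and on the right by the last such
#' jump; if fewer than two jumps exceed the threshold the frame is all belt.
#'
#' @param frame A radial-profile data frame with columns `y` (strictly
#'   increasing lateral position, mm) and `z` (height, mm); an `x` column is
#'   carried through if present.
#' @param threshold Segmentation threshold `T`, mm. Height jumps larger than
#'   this mark the belt-fish boundary; the default of 5 mm sits far above
#'   belt noise and far below the body-edge silhouette jump.
#' @return A list of class `fishcut_segmentation` with tibbles `fish`,
#'   `left_belt`, `right_belt` (concatenating to the input frame) and
#'   `threshold_used`.
#' @export
#' @examples
#' frame <- tibble::tibble(y = 1:8, z = c(0, 0, 0, 10, 12, 10, 0, 0))
#' threshold_segment(frame, threshold = 5)$fish
threshold_segment <- function(frame, threshold = 5) {
  check_number(threshold, "threshold", positive = TRUE)
  if (!is.data.frame(frame) || !all(c("y", "z") %in% names(frame))) {
    stop_invalid("`frame` must be a data frame with columns y and z.")
  }
  n <- nrow(frame)
  if (n == 0L) stop_invalid("`frame` is empty.")
  z <- frame$z
  jumps <- which(abs(diff(z)) > threshold)  # jump i sits between i and i+1
  if (length(jumps) >= 2L && min(jumps) < max(jumps)) {
    i1 <- min(jumps)
    i2 <- max(jumps)
    fish_idx <- (i1 + 1L):i2
    left_idx <- seq_len(i1)
    right_idx <- if (i2 < n) (i2 + 1L):n else integer(0)
  } else {
    fish_idx <- integer(0)
    left_idx <- seq_len(n)
    right_idx <- integer(0)
  }
  structure(
    list(fish = tibble::as_tibble(frame[fish_idx, , drop = FALSE]),
         left_belt = tibble::as_tibble(frame[left_idx, , drop = FALSE]),
         right_belt = tibble::as_tibble(frame[right_idx, , drop = FALSE]),
         threshold_used = threshold),
    class = "fishcut_segmentation"
  )
}

#' Scalar Kalman filtering of a height profile
#'
#' Runs a constant-position (random-walk) scalar Kalman recursion along a
#' height vector: at each step the covariance is inflated by the process
#' covariance, then the state is pulled toward the measurement with gain
#' `K = P / (P + r)`. The state starts at the first measurement with the
#' configured initial covariance. With the default covariances the
#' steady-state gain is small, so high-frequency measurement noise is
#' strongly suppressed while the profile shape is tracked.
#'
#' @param z Height vector, mm.
#' @param config A [filter_config()].
#' @return Filtered height vector of the same length, mm.
#' @export
kalman_filter <- function(z, config = filter_config()) {
  if (length(z) == 0L) stop_invalid("`z` is empty.")
  .kalman_core(as.numeric(z), config$kalman_process_cov,
               config$kalman_measurement_cov, config$kalman_initial_cov)
}

#' Kalman gain sequence
#'
#' Iterates only the covariance recursion of [kalman_filter()] and returns
#' the gain at every step; the sequence converges to the steady-state gain
#' implied by the scalar Riccati fixed point.
#'
#' @param n Number of steps.
#' @param config A [filter_config()].
#' @return Numeric vector of gains in (0, 1).
#' @export
kalman_gains <- function(n, config = filter_config()) {
  .kalman_gain_seq(as.integer(n), config$kalman_process_cov,
                   config$kalman_measurement_cov, config$kalman_initial_cov)
}

#' Sliding-window median filtering of a height profile
#'
#' Replaces each point by the median of the window of offsets
#' `[-median_window_left, +median_window_right]` around it; windows shrink at
#' the edges rather than padding, so no data is invented at the fish
#' boundaries. Removes impulse outliers that survive the Kalman stage.
#'
#' @inheritParams kalman_filter
#' @return Filtered height vector of the same length, mm; its range is
#'   contained in the input range.
#' @export
median_filter <- function(z, config = filter_config()) {
  if (length(z) == 0L) stop_invalid("`z` is empty.")
  .median_core(as.numeric(z), config$median_window_left,
               config$median_window_right)
}

#' Preprocess a whole point cloud
#'
#' Per frame: segment out the belt with [threshold_segment()], keep the fish
#' region, then apply [kalman_filter()] followed by [median_filter()] along
#' the profile (in that order). Frames with no fish points are dropped, as
#' are frames failing a height-consistency check: a genuine belt-fish
#' boundary jump above `threshold` implies the body rises more than
#' `threshold` above the belt, so frames whose filtered fish region never
#' exceeds the local belt level (median of the frame's own belt points) by
#' more than `threshold` are treated as spurious detections (isolated
#' impulse outliers on the belt trigger exactly such frames). Frame
#' positions are preserved.
#'
#' @param cloud Point-cloud tibble with columns `x`, `y`, `z` (mm).
#' @param threshold Segmentation threshold, mm (see [threshold_segment()]).
#' @param config A [filter_config()].
#' @return A point-cloud tibble containing only cleaned fish points.
#' @export
preprocess_cloud <- function(cloud, threshold = 5, config = filter_config()) {
  check_cloud(cloud)
  frames <- split(seq_len(nrow(cloud)), cloud$x)
  out <- purrr::map(frames, function(idx) {
    frame <- cloud[idx, ]
    seg <- threshold_segment(frame, threshold)
    fish <- seg$fish
    if (nrow(fish) == 0L) return(NULL)
    fish$z <- median_filter(kalman_filter(fish$z, config), config)
    belt_z <- c(seg$left_belt$z, seg$right_belt$z)
    if (length(belt_z) > 0L &&
        max(fish$z) - median(belt_z) <= threshold) {
      return(NULL)
    }
    fish
  })
  out <- purrr::compact(out)
  if (length(out) == 0L) {
    rlang::abort(
      sprintf("No fish points found in any of the %d frames (threshold %.3g mm).",
              length(frames), threshold),
      class = "fishcut_empty_result"
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$x, .data$y)
}
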