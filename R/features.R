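# Ventral-dorsal demarcation line extraction and fixed-length resampling.

#' Extract the ventral-dorsal demarcation line
#'
#' The demarcation line is the curve of per-frame maximum heights along the
#' fish: the ridge separating back from belly, and the carrier of the
#' head-cut signal. Heights are reported above the belt plane.
#'
#' @param cloud A cleaned point-cloud tibble (see [preprocess_cloud()]) with
#'   columns `x`, `y`, `z`.
#' @param belt_height Height of the belt plane to subtract, mm.
#' @return A tibble of class `fishcut_demarcation` with columns `x` (frame
#'   position, mm) and `h` (maximum height above belt, mm).
#' @export
extract_demarcation_line <- function(cloud, belt_height = 0) {
  check_cloud(cloud)
  line <- cloud |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(h = max(.data$z) - belt_height, .groups = "drop") |>
    dplyr::arrange(.data$x)
  if (nrow(line) < 2L) {
    stop_invalid("Need at least 2 frames with fish points to form a demarcation line.")
  }
  class(line) <- c("fishcut_demarcation", class(line))
  line
}

#' Resample a demarcation line to a fixed length
#'
#' Linearly interpolates the line heights onto `p` equally spaced positions
#' spanning `[min(x), max(x)]`, so lines from fish of different lengths share
#' one feature dimension. Endpoints are preserved exactly.
#'
#' @param line A demarcation-line tibble with columns `x` and `h`.
#' @param p Number of output positions (default 60).
#' @return Numeric vector of length `p`, mm.
#' @export
resample_line <- function(line, p = 60) {
  if (!is.data.frame(line) || nrow(line) < 2L) {
    stop_invalid("`line` must have at least 2 points.")
  }
  if (p < 2) stop_invalid("`p` must be >= 2.")
  xout <- seq(min(line$x), max(line$x), length.out = p)
  approx(line$x, line$h, xout = xout, ties = "ordered")$y
}

#' Build a feature matrix from demarcation lines
#'
#' Resamples each line to `p` positions (see [resample_line()]) and stacks
#' them into the samples-by-positions feature matrix that feeds the
#' principal-component reduction.
#'
#' @param lines A list of demarcation-line tibbles.
#' @param p Feature length (default 60).
#' @return A tibble with `length(lines)` rows and columns `u01 ... u<p>`.
#' @export
demarcation_features <- function(lines, p = 60) {
  m <- t(vapply(lines, resample_line, numeric(p), p = p))
  colnames(m) <- sprintf("u%02d", seq_len(p))
  tibble::as_tibble(m)
}

#' Z-score standardization of a feature matrix
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator).
#'
#' @param features A samples-by-positions data frame or matrix.
#' @return A list with `values` (standardized matrix), `means` and `sds`
#'   (per-column statistics).
#' @export
standardize_features <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2L) stop_invalid("Need at least 2 samples to standardize.")
  means <- colMeans(m)
  sds <- apply(m, 2, sd)
  bad <- which(sds == 0)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("Zero-variance feature column(s): %s.",
              paste(colnames(m)[bad] %||% bad, collapse = ", ")),
      class = "fishcut_degenerate_column"
    )
  }
  list(values = sweep(sweep(m, 2, means), 2, sds, "/"), means = means, sds = sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
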