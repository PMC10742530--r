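# Parametric spindle-shaped fish bodies on a conveyor belt, scanned by a
# simulated vertical line laser. Every downstream stage of the package is
# testable against the analytic surfaces generated here.

# Size statistics (mm) of the crucian-carp sample population the simulator
# emulates: mean, sd and the min/max truncation bounds for each dimension.
.fish_size_stats <- list(
  head_length    = c(mean = 54.60,  sd = 2.50, min = 50.1,  max = 63.1),
  total_length   = c(mean = 223.60, sd = 8.90, min = 200.8, max = 239.4),
  max_width      = c(mean = 100.90, sd = 2.20, min = 94.6,  max = 103.7),
  max_thickness  = c(mean = 47.49,  sd = 1.85, min = 45.3,  max = 51.54)
)

# Latent size-factor loadings for width and thickness (head loads 1.0, total
# length loads `cor_head_total`). These set the allometric coupling between
# head length and the rest of the body.
.allometry_loadings <- c(max_width = 0.85, max_thickness = 0.985)

#' Sample fish shape parameters
#'
#' Draws shape parameters for spindle-shaped fish from truncated normal
#' marginals matched to the size statistics of the study population, with an
#' allometric dependence structure: a single latent "size" factor drives all
#' four body dimensions (Gaussian copula), so larger fish are simultaneously
#' longer, wider, thicker and have longer heads.
#'
#' @param n Number of fish to sample.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param cor_head_total Latent correlation between head length and total
#'   length (default 0.8).
#' @param peak_frac_mean,peak_frac_sd Mean and sd of the truncated-normal
#'   location of maximum thickness, as a fraction of total length. The default
#'   mean of 1/3 places the thickness peak before one third of the body, as
#'   observed on real ventral-dorsal demarcation lines.
#' @param exponent_mean,exponent_sd Mean and sd of the superellipse exponent
#'   of the body cross-section (4 = boxy/superelliptic, 2 = elliptic).
#'
#' @return A tibble with one row per fish and columns `head_length`,
#'   `total_length`, `max_width`, `max_thickness` (mm),
#'   `thickness_peak_frac` and `cross_section_exponent` (dimensionless).
#' @export
#' @examples
#' sample_fish_params(5, seed = 1)
sample_fish_params <- function(n, seed,
                               cor_head_total = 0.8,
                               peak_frac_mean = 1 / 3, peak_frac_sd = 0.025,
                               exponent_mean = 4, exponent_sd = 0.3) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_invalid("`n` must be a count >= 1.")
  }
  n <- as.integer(n)
  if (cor_head_total <= 0 || cor_head_total >= 1) {
    stop_invalid("`cor_head_total` must be in (0, 1).")
  }
  loadings <- c(head_length = 1.0, total_length = cor_head_total,
                .allometry_loadings)
  withr::with_seed(seed, {
    s <- rnorm(n)  # latent size factor
    body <- purrr::imap(.fish_size_stats, function(st, nm) {
      lam <- loadings[[nm]]
      zlat <- lam * s + sqrt(1 - lam^2) * rnorm(n)
      qtruncnorm(pnorm(zlat), st[["mean"]], st[["sd"]], st[["min"]], st[["max"]])
    })
    peak <- qtruncnorm(runif(n), peak_frac_mean, peak_frac_sd, 0.25, 0.45)
    expo <- qtruncnorm(runif(n), exponent_mean, exponent_sd, 3, 5)
  })
  tibble::tibble(
    head_length = body$head_length,
    total_length = body$total_length,
    max_width = body$max_width,
    max_thickness = body$max_thickness,
    thickness_peak_frac = peak,
    cross_section_exponent = expo
  )
}

#' Longitudinal thickness envelope of a fish body
#'
#' The ridge-line (maximum height over the cross-section) of the analytic
#' fish surface as a function of the position along the body. The envelope is
#' the C1-smooth unimodal bump
#' `t(u) = max_thickness * ((u/up)^up * ((1-u)/(1-up))^(1-up))` with
#' `u = x / total_length` and `up = thickness_peak_frac`: it rises steeply
#' from the mouth, attains exactly `max_thickness` at `u = up`, and declines
#' more slowly toward the tail.
#'
#' @param params One-row data frame (or list) of fish shape parameters as
#'   returned by [sample_fish_params()].
#' @param x Position(s) along the body, mm, measured from the mouth.
#' @return Envelope height(s) in mm; 0 outside `[0, total_length]`.
#' @export
fish_envelope <- function(params, x) {
  L <- params$total_length
  up <- params$thickness_peak_frac
  u <- x / L
  t <- numeric(length(u))
  inside <- u > 0 & u < 1
  ui <- u[inside]
  t[inside] <- params$max_thickness *
    (ui / up)^up * ((1 - ui) / (1 - up))^(1 - up)
  t
}

# Plan-view half-width of the body at longitudinal position x (elliptic
# outline; widest at mid-body).
fish_halfwidth <- function(params, x) {
  u <- x / params$total_length
  w <- numeric(length(u))
  inside <- u > 0 & u < 1
  w[inside] <- (params$max_width / 2) * sqrt(4 * u[inside] * (1 - u[inside]))
  w
}

#' Analytic fish surface height
#'
#' Height of the fish upper surface above the belt at longitudinal position
#' `x` and lateral position `y` (both mm; `y = 0` is the body midline). The
#' cross-section is the superelliptic dome
#' `z = t(x) * (1 - |y / w(x)|^e)^(1/e)` with `e = cross_section_exponent`,
#' laterally symmetric and maximal on the midline; `t(x)` is the
#' [fish_envelope()] and `w(x)` the plan-view half-width. Returns 0 outside
#' the body footprint.
#'
#' @inheritParams fish_envelope
#' @param y Lateral position(s), mm.
#' @return Height(s) in mm above the belt plane.
#' @export
fish_height <- function(params, x, y) {
  nn <- max(length(x), length(y))
  x <- rep_len(x, nn)
  y <- rep_len(y, nn)
  t <- fish_envelope(params, x)
  w <- fish_halfwidth(params, x)
  z <- numeric(nn)
  e <- params$cross_section_exponent
  inside <- w > 0 & abs(y) < w
  z[inside] <- t[inside] * (1 - abs(y[inside] / w[inside])^e)^(1 / e)
  z
}

#' Line-laser scan configuration
#'
#' Geometry and noise settings of the simulated scanner. Defaults follow the
#' physical rig the simulator emulates: 640 points per laser line, a belt
#' plane at 250.32 mm in the sensor frame, and a frame every 3 mm of belt
#' travel.
#'
#' @param points_per_line Number of lateral samples per laser frame.
#' @param frame_spacing Belt travel between sampled frames, mm.
#' @param belt_height Height of the belt plane in the sensor frame, mm.
#' @param lateral_span Width covered by the laser line, mm; must exceed the
#'   width of any scanned fish.
#' @param belt_margin Belt-only distance scanned before and after the fish,
#'   mm.
#' @param gaussian_noise_sd Per-point Gaussian measurement noise sd, mm.
#' @param impulse_rate Probability that a point is an impulse outlier.
#' @param impulse_magnitude Magnitude of impulse outliers, mm (sign random).
#' @param vibration_amplitude Amplitude of the per-frame sinusoidal conveyor
#'   vibration offset, mm.
#' @param seed Integer seed for the noise streams.
#' @return A list of class `fishcut_scan_config`.
#' @export
scan_config <- function(points_per_line = 640,
                        frame_spacing = 3,
                        belt_height = 250.32,
                        lateral_span = 150,
                        belt_margin = 9,
                        gaussian_noise_sd = 0.3,
                        impulse_rate = 0.01,
                        impulse_magnitude = 5,
                        vibration_amplitude = 0.2,
                        seed = 1L) {
  check_number(points_per_line, "points_per_line", positive = TRUE)
  if (points_per_line < 2) stop_invalid("`points_per_line` must be >= 2.")
  check_number(frame_spacing, "frame_spacing", positive = TRUE)
  check_number(lateral_span, "lateral_span", positive = TRUE)
  check_number(belt_margin, "belt_margin", nonneg = TRUE)
  check_number(gaussian_noise_sd, "gaussian_noise_sd", nonneg = TRUE)
  check_number(impulse_rate, "impulse_rate", nonneg = TRUE)
  check_number(impulse_magnitude, "impulse_magnitude", nonneg = TRUE)
  check_number(vibration_amplitude, "vibration_amplitude", nonneg = TRUE)
  structure(
    list(points_per_line = as.integer(points_per_line),
         frame_spacing = frame_spacing, belt_height = belt_height,
         lateral_span = lateral_span, belt_margin = belt_margin,
         gaussian_noise_sd = gaussian_noise_sd, impulse_rate = impulse_rate,
         impulse_magnitude = impulse_magnitude,
         vibration_amplitude = vibration_amplitude,
         seed = as.integer(seed)),
    class = "fishcut_scan_config"
  )
}

#' Simulate a line-laser scan of one fish
#'
#' Generates one radial profile per belt position: the fish surface height
#' (see [fish_height()]) on top of the belt plane, with additive Gaussian
#' measurement noise, sparse impulse outliers, and a per-frame sinusoidal
#' vibration offset. The fish mouth sits at conveyor position
#' `x = belt_margin`, so belt-only frames precede and follow the body.
#'
#' @inheritParams fish_envelope
#' @param config A [scan_config()]; the scan is deterministic given
#'   `config$seed`.
#' @return A point-cloud tibble with columns `x` (conveyor position of the
#'   frame, mm), `y` (lateral position, mm) and `z` (measured height, mm),
#'   ordered by `x` then `y`.
#' @export
simulate_scan <- function(params, config = scan_config()) {
  if (params$max_width >= config$lateral_span) {
    stop_invalid("Fish is wider than the lateral span of the laser.")
  }
  L <- params$total_length
  xs <- seq(0, L + 2 * config$belt_margin, by = config$frame_spacing)
  ygrid <- seq(-config$lateral_span / 2, config$lateral_span / 2,
               length.out = config$points_per_line)
  n_frames <- length(xs)
  npt <- config$points_per_line
  surf <- vapply(xs - config$belt_margin,
                 function(xf) fish_height(params, xf, ygrid),
                 numeric(npt))
  withr::with_seed(config$seed, {
    phase <- runif(1, 0, 2 * pi)
    gauss <- matrix(rnorm(npt * n_frames, sd = config$gaussian_noise_sd),
                    nrow = npt)
    hit <- matrix(runif(npt * n_frames) < config$impulse_rate, nrow = npt)
    sign <- matrix(sample(c(-1, 1), npt * n_frames, replace = TRUE), nrow = npt)
  })
  vib <- config$vibration_amplitude *
    sin(2 * pi * (seq_len(n_frames) - 1) / 12 + phase)
  z <- config$belt_height + surf + gauss +
    matrix(vib, nrow = npt, ncol = n_frames, byrow = TRUE) +
    hit * sign * config$impulse_magnitude
  tibble::tibble(
    x = rep(xs, each = npt),
    y = rep(ygrid, times = n_frames),
    z = as.vector(z)
  )
}

#' Generate a synthetic scan dataset
#'
#' Composes [sample_fish_params()] and [simulate_scan()] into a dataset of
#' `n` fish passes with known ground-truth head lengths, the regression
#' target of the whole pipeline.
#'
#' @param n Number of fish.
#' @param config A [scan_config()]; its `seed` is ignored — per-fish scan
#'   seeds are derived from `seed`.
#' @param seed Integer seed governing both the shape draw and every scan.
#' @param ... Passed on to [sample_fish_params()].
#' @return An object of class `fishcut_dataset`: a list with `clouds` (list
#'   of point-cloud tibbles), `head_lengths` (mm), `params` (tibble of shape
#'   parameters) and the `config` used.
#' @export
generate_dataset <- function(n, config = scan_config(), seed = 1L, ...) {
  params <- sample_fish_params(n, seed = sub_seed(seed, 0), ...)
  clouds <- purrr::map(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- sub_seed(seed, i)
    simulate_scan(params[i, ], cfg)
  })
  structure(
    list(clouds = clouds, head_lengths = params$head_length,
         params = params, config = config, seed = as.integer(seed)),
    class = "fishcut_dataset"
  )
}

#' @export
print.fishcut_dataset <- function(x, ...) {
  cat(sprintf(
    "<fishcut_dataset> %d fish, %d-point laser lines, frame spacing %.3g mm\n",
    length(x$clouds), x$config$points_per_line, x$config$frame_spacing))
  cat(sprintf("head lengths: %.1f-%.1f mm (mean %.1f)\n",
              min(x$head_lengths), max(x$head_lengths), mean(x$head_lengths)))
  invisible(x)
}
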