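# File formats and configuration: point clouds round-trip through long-form
# CSV (text) or a native RDS container (binary, frames + metadata); pipeline
# configuration round-trips through YAML.

provenance_line <- function(seed = NULL) {
  sprintf("# fishcut %s%s",
          as.character(utils::packageVersion("fishcut")),
          if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
}

#' Write a point cloud to disk
#'
#' `csv` writes long-form comma-separated text with header `x,y,z` (mm,
#' dot decimal, UTF-8) and a `#`-prefixed provenance comment line; `rds`
#' writes a native container holding the frame matrices, frame positions and
#' metadata.
#'
#' @param cloud Point-cloud tibble with columns `x`, `y`, `z`.
#' @param path Output file path.
#' @param format `"csv"` or `"rds"`.
#' @param seed Optional seed recorded in the provenance metadata.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("csv", "rds"),
                              seed = NULL) {
  format <- match.arg(format)
  check_cloud(cloud)
  if (format == "csv") {
    writeLines(provenance_line(seed), path)
    readr::write_csv(cloud[, c("x", "y", "z")], path, append = TRUE,
                     col_names = TRUE)
  } else {
    frames <- split(cloud[, c("y", "z")], cloud$x)
    saveRDS(list(provenance = provenance_line(seed),
                 frame_x = as.numeric(names(frames)),
                 frames = purrr::map(frames, as.matrix)),
            path)
  }
  invisible(path)
}

#' Read a point cloud from disk
#'
#' Reads either format written by [write_point_cloud()]. Rows are grouped by
#' frame position `x` and sorted by `y` within each frame, so a shuffled CSV
#' loads to the same cloud.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"rds"`.
#' @return A point-cloud tibble with columns `x`, `y`, `z` (mm).
#' @export
read_point_cloud <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  if (format == "rds") {
    obj <- readRDS(path)
    cloud <- purrr::map2_dfr(obj$frame_x, obj$frames, function(x, m) {
      tibble::tibble(x = x, y = m[, "y"], z = m[, "z"])
    })
  } else {
    cloud <- tryCatch(
      readr::read_csv(path, comment = "#", show_col_types = FALSE,
                      col_types = readr::cols(.default = readr::col_double())),
      error = function(e) {
        rlang::abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
                     class = "fishcut_parse_error")
      })
    if (nrow(cloud) == 0L) {
      rlang::abort(sprintf("No data rows in %s.", path),
                   class = "fishcut_parse_error")
    }
    if (!all(c("x", "y", "z") %in% names(cloud))) {
      rlang::abort(sprintf("%s must have columns x,y,z.", path),
                   class = "fishcut_parse_error")
    }
    prob <- readr::problems(cloud)
    if (nrow(prob) > 0L) {
      rlang::abort(sprintf("Malformed row at line %d of %s.", prob$row[1], path),
                   class = "fishcut_parse_error")
    }
  }
  cloud <- dplyr::arrange(cloud, .data$x, .data$y)
  dup <- cloud |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(bad = anyDuplicated(.data$y) > 0, .groups = "drop")
  if (any(dup$bad)) {
    rlang::abort("Duplicate lateral positions within a frame.",
                 class = "fishcut_validation_error")
  }
  cloud
}

# Default nested pipeline configuration. Every leaf is overridable from a
# YAML file; unknown keys are rejected by name.
default_pipeline_config <- function() {
  list(
    n_fish = 204L,
    seed = 1L,
    scan = list(points_per_line = 640L, frame_spacing = 3, belt_height = 250.32,
                lateral_span = 150, belt_margin = 9, gaussian_noise_sd = 0.3,
                impulse_rate = 0.01, impulse_magnitude = 5,
                vibration_amplitude = 0.2),
    preprocess = list(threshold = 5, kalman_process_cov = 1e-4,
                      kalman_measurement_cov = 0.1, kalman_initial_cov = 1,
                      median_window_left = 2L, median_window_right = 1L),
    features = list(p = 60L, variance_target = 0.95),
    split = list(n_train = 154L, n_test = 50L),
    models = c("lssvm", "psobp", "lstm")
  )
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      rlang::abort(sprintf("Unknown configuration key: %s", here),
                   class = "fishcut_config_error")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) {
        rlang::abort(sprintf("Key %s must be a section.", here),
                     class = "fishcut_config_error")
      }
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()], starting from
#' the package defaults and applying overrides. Unknown keys are rejected
#' with the offending name. Round-trips losslessly through YAML via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param ... Named overrides of top-level keys (`n_fish`, `seed`, `models`)
#'   or whole sections (`scan`, `preprocess`, `features`, `split`) given as
#'   named lists.
#' @return A list of class `fishcut_config`.
#' @export
#' @examples
#' pipeline_config(n_fish = 20, scan = list(gaussian_noise_sd = 0))
pipeline_config <- function(...) {
  cfg <- merge_config(default_pipeline_config(), list(...))
  structure(cfg, class = "fishcut_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), obj)
  structure(cfg, class = "fishcut_config")
}

#' @rdname pipeline_config
#' @param config A `fishcut_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
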