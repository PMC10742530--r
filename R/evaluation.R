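# Train/test splitting, regression metrics (R2, RMSE, MAE, RPD) and the
# end-to-end model comparison report.

#' Random train/test split
#'
#' Uniform random partition without replacement; the defaults reproduce the
#' 204 = 154 + 50 design of the study population.
#'
#' @param n_total Number of samples available.
#' @param n_train,n_test Training and test set sizes (defaults 154 and 50).
#' @param seed Integer seed; the split is deterministic given `seed`.
#' @return A list of class `fishcut_split` with integer vectors `train` and
#'   `test` (disjoint) and the sizes used.
#' @export
make_split <- function(n_total, n_train = 154, n_test = 50, seed = 1L) {
  if (n_train + n_test > n_total) {
    stop_invalid("`n_train + n_test` exceeds `n_total`.")
  }
  if (n_train < 1 || n_test < 1) stop_invalid("Split sizes must be >= 1.")
  idx <- withr::with_seed(seed, sample(n_total, n_train + n_test))
  structure(
    list(train = sort(idx[seq_len(n_train)]),
         test = sort(idx[n_train + seq_len(n_test)]),
         n_total = n_total, n_train = as.integer(n_train),
         n_test = as.integer(n_test), seed = as.integer(seed)),
    class = "fishcut_split"
  )
}

#' Regression evaluation metrics
#'
#' Computes the four indicators used to judge head-cut identification
#' models: the coefficient of determination `R2 = 1 - SS_res / SS_tot`, the
#' root mean square error, the mean absolute error, and the residual
#' predictive deviation `RPD = SD(y_true) / RMSE` (sample SD, n - 1). The
#' algebraically related form `1 / sqrt(1 - R2)` is reported as
#' `rpd_from_r2`; the two differ in finite samples. An RPD above 2.5 is read
#' as "accurate and reliable", an R2 above 0.82 as usable in practice and
#' above 0.9 as excellent.
#'
#' @param y_true Observed values, mm; must not be constant.
#' @param y_pred Predicted values, mm, same length.
#' @return A one-row tibble with columns `r2`, `rmse`, `mae`, `rpd`,
#'   `rpd_from_r2` and `n`.
#' @export
#' @examples
#' compute_metrics(c(0, 2), c(1, 1))
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_invalid("Length mismatch.")
  if (length(y_true) < 2L) stop_invalid("Need at least 2 observations.")
  if (var(y_true) == 0) {
    rlang::abort("R2 is undefined for constant observed values.",
                 class = "fishcut_undefined_r2")
  }
  res <- y_true - y_pred
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sum((y_true - mean(y_true))^2)
  tibble::tibble(
    r2 = r2,
    rmse = rmse,
    mae = mean(abs(res)),
    rpd = if (rmse == 0) Inf else sd(y_true) / rmse,
    rpd_from_r2 = if (r2 >= 1) Inf else 1 / sqrt(1 - r2),
    n = length(y_true)
  )
}

# Interpretation bands applied to test-set metrics.
metric_bands <- function(r2, rpd) {
  dplyr::case_when(
    rpd > 2.5 & r2 > 0.9 ~ "excellent, accurate and reliable",
    rpd > 2.5 ~ "accurate and reliable",
    r2 > 0.9 ~ "excellent fit",
    r2 > 0.82 ~ "practical",
    rpd < 1.4 ~ "poor reliability",
    TRUE ~ "limited"
  )
}

#' Evaluate the full pipeline on a dataset
#'
#' Runs preprocessing, demarcation-line extraction, PCA reduction, a random
#' train/test split and the requested regressors on a scan dataset, and
#' reports train and test metrics per model together with the standard
#' interpretation bands (reliable if RPD > 2.5; practical if R2 > 0.82;
#' excellent if R2 > 0.9).
#'
#' @param dataset A `fishcut_dataset` (see [generate_dataset()]), or a list
#'   with `clouds`, `head_lengths` and a `config` carrying `belt_height`.
#' @param models Character vector among `"lssvm"`, `"psobp"`, `"lstm"`.
#' @param threshold Segmentation threshold, mm.
#' @param filter A [filter_config()].
#' @param p Demarcation-line feature length (default 60).
#' @param variance_target PCA cumulative-variance selection rule.
#' @param n_train,n_test Split sizes.
#' @param seed Integer seed driving the split and every model fit.
#' @param verbose Log stage progress via `message()`.
#' @return An object of class `fishcut_report`: a list with `metrics`
#'   (tibble: model, split, r2, rmse, mae, rpd, rpd_from_r2, n, band),
#'   `predictions` (tibble of per-fish observed/predicted values),
#'   `pca`, `split` and the fitted `models`.
#' @export
evaluate_pipeline <- function(dataset,
                              models = c("lssvm", "psobp", "lstm"),
                              threshold = 5,
                              filter = filter_config(),
                              p = 60,
                              variance_target = 0.95,
                              n_train = 154, n_test = 50,
                              seed = 1L,
                              verbose = FALSE) {
  if (length(models) == 0L) stop_invalid("Request at least one model.")
  models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  n <- length(dataset$clouds)
  belt <- dataset$config$belt_height
  say("Preprocessing %d clouds", n)
  lines <- purrr::map(dataset$clouds, function(cl) {
    extract_demarcation_line(preprocess_cloud(cl, threshold, filter),
                             belt_height = belt)
  })
  say("Extracted %d demarcation lines; resampling to p = %d", length(lines), p)
  features <- demarcation_features(lines, p = p)
  pca <- pca_fit(features, variance_target = variance_target)
  scores <- pca_transform(pca, features)
  say("PCA retained %d components (%.2f%% variance)", pca$n_selected,
      100 * sum(pca$explained[seq_len(pca$n_selected)]))
  split <- make_split(n, n_train, n_test, seed = sub_seed(seed, 1))
  y <- dataset$head_lengths
  Xtr <- scores[split$train, , drop = FALSE]
  Xte <- scores[split$test, , drop = FALSE]
  fit_one <- function(kind) {
    say("Training %s on %d samples", kind, split$n_train)
    switch(kind,
      lssvm = tune_lssvm(Xtr, y[split$train],
                         config = pso_config(max_iter = 100,
                                             seed = sub_seed(seed, 2))),
      psobp = pso_bp_fit(Xtr, y[split$train],
                         pso = pso_config(seed = sub_seed(seed, 3)),
                         net = bp_network(n_input = ncol(Xtr),
                                          seed = sub_seed(seed, 4))),
      lstm = lstm_fit(Xtr, y[split$train],
                      model = lstm_model(seed = sub_seed(seed, 5)),
                      validation = list(X = Xte, y = y[split$test]))
    )
  }
  fits <- purrr::map(models, fit_one)
  names(fits) <- models
  metrics <- purrr::map_dfr(models, function(kind) {
    fit <- fits[[kind]]
    dplyr::bind_rows(
      dplyr::mutate(compute_metrics(y[split$train], predict(fit, Xtr)),
                    model = kind, split = "train", .before = 1),
      dplyr::mutate(compute_metrics(y[split$test], predict(fit, Xte)),
                    model = kind, split = "test", .before = 1)
    )
  })
  metrics$band <- metric_bands(metrics$r2, metrics$rpd)
  predictions <- purrr::map_dfr(models, function(kind) {
    idx <- c(split$train, split$test)
    tibble::tibble(
      model = kind,
      fish = idx,
      split = rep(c("train", "test"), c(split$n_train, split$n_test)),
      observed = y[idx],
      predicted = c(predict(fits[[kind]], Xtr), predict(fits[[kind]], Xte))
    )
  })
  structure(
    list(metrics = metrics, predictions = predictions, pca = pca,
         split = split, models = fits, seed = as.integer(seed)),
    class = "fishcut_report"
  )
}

#' @export
print.fishcut_report <- function(x, ...) {
  cat(sprintf("<fishcut_report> %d fish (%d train / %d test)\n",
              x$split$n_total, x$split$n_train, x$split$n_test))
  m <- dplyr::filter(x$metrics, .data$split == "test")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-6s test R2 %.4f RMSE %.4f MAE %.4f RPD %.4f  [%s]\n",
                m$model[i], m$r2[i], m$rmse[i], m$mae[i], m$rpd[i], m$band[i]))
  }
  invisible(x)
}

#' Tidy a pipeline report
#'
#' @param x A `fishcut_report`.
#' @param ... Unused.
#' @return The metrics tibble (one row per model and split).
#' @method tidy fishcut_report
#' @export
tidy.fishcut_report <- function(x, ...) x$metrics

#' @rdname tidy.fishcut_report
#' @method glance fishcut_report
#' @export
glance.fishcut_report <- function(x, ...) {
  best <- x$metrics |>
    dplyr::filter(.data$split == "test") |>
    dplyr::slice_max(.data$r2, n = 1)
  tibble::tibble(
    n_total = x$split$n_total, n_train = x$split$n_train,
    n_test = x$split$n_test,
    n_components = x$pca$n_selected,
    cumulative_variance = sum(x$pca$explained[seq_len(x$pca$n_selected)]),
    best_model = best$model, best_r2 = best$r2, best_rpd = best$rpd
  )
}
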