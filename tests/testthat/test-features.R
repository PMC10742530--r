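test_that("demarcation line reproduces the analytic envelope on noiseless scans", {
  cfg <- noiseless_config()
  ds <- generate_dataset(6, cfg, seed = 6)
  for (i in seq_len(6)) {
    cloud <- ds$clouds[[i]]
    segged <- dplyr::bind_rows(lapply(split(cloud, cloud$x), function(fr) {
      threshold_segment(fr, 5)$fish
    }))
    line <- extract_demarcation_line(segged, belt_height = cfg$belt_height)
    env <- fish_envelope(ds$params[i, ], line$x - cfg$belt_margin)
    expect_lt(max(abs(line$h - env)), 1e-3)
    # the ridge maximum sits in the front half of the body
    expect_lt(line$x[which.max(line$h)] - cfg$belt_margin,
              0.5 * ds$params$total_length[i])
  }
})

test_that("single-point frames and too-short clouds are handled", {
  toy <- tibble::tibble(x = c(1, 2, 3), y = c(0, 0, 0), z = c(5, 9, 4))
  line <- extract_demarcation_line(toy, belt_height = 1)
  expect_equal(line$h, c(4, 8, 3))
  expect_error(extract_demarcation_line(toy[1, ], belt_height = 1),
               class = "fishcut_invalid_argument")
})

test_that("resampling is exact on aligned grids and linear ramps, and matches a pointwise oracle", {
  # identity: already sampled at p equally spaced points
  line <- tibble::tibble(x = seq(0, 10, length.out = 25),
                         h = sin(seq(0, 3, length.out = 25)) + 2)
  expect_equal(resample_line(line, 25), line$h)
  # exactness on a linear ramp at any p
  ramp <- tibble::tibble(x = c(0, 1.3, 2.9, 7, 10), h = 3 + 0.7 * c(0, 1.3, 2.9, 7, 10))
  expect_equal(resample_line(ramp, 17), 3 + 0.7 * seq(0, 10, length.out = 17))
  # endpoints preserved exactly
  withr::with_seed(14, {
    rl <- tibble::tibble(x = sort(runif(31, 0, 200)), h = runif(31, 0, 50))
  })
  got <- resample_line(rl, 60)
  expect_equal(got[1], rl$h[1])
  expect_equal(got[60], rl$h[31])
  # pointwise piecewise-linear oracle
  xout <- seq(min(rl$x), max(rl$x), length.out = 60)
  want <- vapply(xout, function(x0) oracle_interp(rl$x, rl$h, x0), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(resample_line(rl[1, ], 60), class = "fishcut_invalid_argument")
  expect_error(resample_line(rl, 1), class = "fishcut_invalid_argument")
})

test_that("z-score standardization matches a direct summation oracle", {
  s <- standardize_features(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(s$values), c(-1, 0, 1))
  withr::with_seed(15, m <- matrix(rnorm(20, 5, 3), 5, 4))
  s <- standardize_features(m)
  for (j in 1:4) {
    mu <- sum(m[, j]) / 5
    sdj <- sqrt(sum((m[, j] - mu)^2) / 4)
    expect_equal(s$means[[j]], mu)
    expect_equal(s$sds[[j]], sdj)
    expect_equal(s$values[, j], (m[, j] - mu) / sdj)
  }
  expect_true(all(abs(colMeans(s$values)) < 1e-10))
  bad <- m
  bad[, 3] <- 7
  colnames(bad) <- paste0("u0", 1:4)
  err <- tryCatch(standardize_features(bad), error = identity)
  expect_s3_class(err, "fishcut_degenerate_column")
  expect_match(conditionMessage(err), "u03")
})

test_that("correlation-matrix PCA: closed forms, trace identity, reconstruction, oracle eigenpairs", {
  # rank-1: two perfectly correlated columns
  m <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  fit <- pca_fit(m)
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_identical(fit$n_selected, 1L)
  expect_equal(fit$explained[1], 1)
  # two columns with sample correlation rho: eigenvalues 1 +/- rho
  withr::with_seed(16, m2 <- matrix(rnorm(40), 20, 2))
  rho <- cor(m2[, 1], m2[, 2])
  fit2 <- pca_fit(m2)
  expect_equal(fit2$eigenvalues, c(1 + abs(rho), 1 - abs(rho)), tolerance = 1e-12)

  withr::with_seed(17, m3 <- matrix(rnorm(60), 10, 6))
  fit3 <- pca_fit(m3)
  expect_equal(sum(fit3$eigenvalues), 6, tolerance = 1e-8)
  expect_true(all(diff(fit3$eigenvalues) <= 1e-12))
  expect_true(all(diff(cumsum(fit3$explained)) >= -1e-12))
  # loadings orthonormal
  expect_equal(crossprod(fit3$loadings), diag(6), tolerance = 1e-8)
  # full-rank reconstruction of the standardized matrix
  Z <- standardize_features(m3)$values
  expect_equal((Z %*% fit3$loadings) %*% t(fit3$loadings), Z, tolerance = 1e-8)
  # brute-force eigensolver oracle (power iteration with deflation)
  D <- crossprod(Z) / 9
  ora <- oracle_eigen_sym(D)
  expect_equal(fit3$eigenvalues, ora$values, tolerance = 1e-8)
  for (j in 1:6) {
    align <- abs(sum(fit3$loadings[, j] * ora$vectors[, j]))
    expect_equal(align, 1, tolerance = 1e-6)
  }
  expect_error(pca_fit(matrix(c(1, NA, 3, 4, 5, 7), 3, 2)),
               class = "fishcut_invalid_argument")
  expect_error(pca_fit(m3, variance_target = 0), class = "fishcut_invalid_argument")
})

test_that("PCA projection: centered training scores, determinism, conventions", {
  withr::with_seed(18, m <- matrix(rnorm(200), 20, 10))
  fit <- pca_fit(m, variance_target = 0.95)
  sc <- pca_transform(fit, m)
  expect_identical(ncol(sc), fit$n_selected)
  expect_true(all(abs(colMeans(as.matrix(sc))) < 1e-10))
  # coefficient convention sqrt: unit-variance training scores
  expect_equal(unname(apply(as.matrix(sc), 2, var)), rep(1, ncol(sc)),
               tolerance = 1e-8)
  # duplicate input row gives a duplicate score row
  m2 <- rbind(m[1, ], m)
  sc2 <- pca_transform(fit, m2)
  expect_equal(unlist(sc2[1, ]), unlist(sc2[2, ]))
  # literal printed convention differs by a further 1/sqrt(lambda)
  lit <- pca_fit(m, coefficient_convention = "literal")
  ratio <- fit$coefficients[, 1] / lit$coefficients[, 1]
  expect_equal(unique(round(ratio, 8)), round(sqrt(fit$eigenvalues[1]), 8))
  expect_error(pca_transform(fit, m[, 1:4]), class = "fishcut_invalid_argument")
})

test_that("three components capture the variance of synthetic demarcation lines", {
  cfg <- test_scan_config()
  ds <- generate_dataset(60, cfg, seed = 19)
  lines <- purrr::map(ds$clouds, function(cl) {
    extract_demarcation_line(preprocess_cloud(cl), belt_height = cfg$belt_height)
  })
  feat <- demarcation_features(lines, p = 60)
  fit <- pca_fit(feat)
  expect_gte(sum(fit$explained[1:3]), 0.9)
  expect_lte(fit$n_selected, 5L)
})
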