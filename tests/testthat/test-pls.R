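# Build a calibration tibble from an explicit matrix and labels.
cal_tbl <- function(x, y, wl = seq(1400, 2400, length.out = ncol(x))) {
  colnames(x) <- as.character(wl)
  dplyr::bind_cols(
    tibble::tibble(phantom_id = sprintf("P%02d", seq_len(nrow(x))),
                   glucose_mgdl = y),
    tibble::as_tibble(x)
  )
}

test_that("one factor suffices for noiseless single-component spectra", {
  wl <- wavelength_grid(40)
  eps <- exp(-0.5 * ((wl - 2100) / 45)^2) * 3e-7
  conc <- c(0, 82.5, 167.5, 250, 332.5, 417.5, 500)
  data <- cal_tbl(outer(conc, eps), conc, wl)
  fit <- fit_pls(data, n_factors = 1)
  expect_equal(predict(fit, data), conc, tolerance = 1e-8)
})

test_that("SIMPLS at maximal factors matches the least-squares oracle", {
  withr::with_seed(31, {
    x <- matrix(rnorm(30), 6, 5)
    y <- rnorm(6)
  })
  data <- cal_tbl(x, y)
  fit <- fit_pls(data, n_factors = 5)
  # brute-force pseudoinverse oracle on centered data
  xc <- scale(x, scale = FALSE)
  b <- solve(crossprod(xc), crossprod(xc, y - mean(y)))
  oracle <- as.vector(xc %*% b) + mean(y)
  expect_equal(predict(fit, data), oracle, tolerance = 1e-8)
})

test_that("predictions are invariant to wavelength column order", {
  withr::with_seed(32, {
    x <- matrix(rnorm(80), 8, 10)
    y <- rnorm(8)
  })
  data <- cal_tbl(x, y)
  perm <- sample(10)
  data_perm <- data[, c(1, 2, 2 + perm)]
  f1 <- fit_pls(data, n_factors = 3)
  f2 <- fit_pls(data_perm, n_factors = 3)
  expect_equal(predict(f1, data), predict(f2, data_perm), tolerance = 1e-10)
})

test_that("prediction is a well-behaved affine map", {
  withr::with_seed(33, {
    x <- matrix(rnorm(120), 12, 10)
    y <- rnorm(12, 250, 100)
  })
  data <- cal_tbl(x, y)
  fit <- fit_pls(data, n_factors = 4)
  # training-mean spectrum predicts the training-mean label
  expect_equal(predict(fit, matrix(colMeans(x), 1)), mean(y))
  # zero-factor degenerate model returns the mean for anything
  expect_equal(predict(fit, x[3, ], n_factors = 0), mean(y))
  # affine: predict(a s1 + (1-a) s2) interpolates the predictions
  a <- 0.3
  mix <- a * x[1, ] + (1 - a) * x[2, ]
  expect_equal(predict(fit, mix),
               a * predict(fit, x[1, , drop = FALSE]) +
                 (1 - a) * predict(fit, x[2, , drop = FALSE]))
  expect_error(fit_pls(data, n_factors = 50), "1..")
})

test_that("rank deficiency reports the attainable maximum", {
  x <- outer(1:6, c(1, 2, 3, 4))  # rank 1
  data <- cal_tbl(x, rnorm(6))
  expect_error(fit_pls(data, n_factors = 3), "only 1 factor")
})

test_that("SECV uses the plain-N denominator and ignores pair order", {
  expect_equal(secv(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(secv(c(0, 100), c(10, 90)), 10)  # sqrt(200 / 2)
  withr::with_seed(34, {
    a <- rnorm(20); p <- rnorm(20); o <- sample(20)
  })
  expect_equal(secv(a, p), secv(a[o], p[o]))
  expect_error(secv(1:3, 1:4), "length")
})

test_that("leave-one-phantom-out matches a from-scratch refit loop", {
  withr::with_seed(35, {
    x <- matrix(rnorm(15 * 20), 15, 20)
    y <- rnorm(15, 250, 150)
  })
  data <- cal_tbl(x, y)
  cv <- lopo_cv(data, n_factors = 3)
  expect_equal(nrow(cv$predictions), 15)
  naive <- vapply(seq_len(15), function(i) {
    predict(fit_pls(data[-i, ], n_factors = 3), data[i, ])
  }, double(1))
  expect_equal(cv$predictions$predicted_mgdl, naive, tolerance = 1e-10)
  expect_equal(cv$secv_mgdl, secv(y, naive))

  # exact model class: noiseless one-component data cross-validates to ~0
  wl <- wavelength_grid(30)
  eps <- exp(-0.5 * ((wl - 2100) / 45)^2) * 3e-7
  conc <- rep(c(0, 100, 250, 400, 500), 3)
  clean <- cal_tbl(outer(conc, eps), conc, wl)
  expect_lt(lopo_cv(clean, n_factors = 1)$secv_mgdl, 1e-6)
})

test_that("the grid search enumerates the lattice and finds the true minimum", {
  d <- table1_design()
  ds <- simulate_calibration_dataset(d, "laser", seed = 3)
  gs <- grid_search(ds, min_width_nm = 300, width_step_nm = 400,
                    start_step_nm = 300, factors = c(2, 4, 6))
  # brute-force double loop over the recorded windows
  brute <- purrr::pmap_dbl(
    dplyr::distinct(gs$surface, start_nm, end_nm),
    function(start_nm, end_nm) {
      min(secv_curve(ds, factors = c(2, 4, 6),
                     window = c(start_nm, end_nm))$secv_mgdl)
    })
  expect_equal(min(gs$surface$secv_mgdl), min(brute))
  expect_equal(gs$optimum$secv_mgdl, min(gs$surface$secv_mgdl))
  # tie-break: no surface row beats the optimum under (secv, factors, width, start)
  o <- gs$optimum
  better <- dplyr::filter(gs$surface, secv_mgdl < o$secv_mgdl |
    (secv_mgdl == o$secv_mgdl & n_factors < o$n_factors))
  expect_equal(nrow(better), 0)
  expect_s3_class(tidy(gs), "tbl_df")
  expect_equal(nrow(glance(gs)), 1)
})

test_that("regression diagnostics recover slope, intercept and R2", {
  y <- seq(0, 500, length.out = 20)
  perfect <- tibble::tibble(glucose_mgdl = y, predicted_mgdl = y)
  # exact inputs trigger lm's "essentially perfect fit" warning by design
  dg <- suppressWarnings(regression_diagnostics(perfect))
  expect_equal(dg$slope, 1)
  expect_equal(dg$intercept, 0, tolerance = 1e-10)
  expect_equal(dg$r_squared, 1)

  shifted <- tibble::tibble(glucose_mgdl = y, predicted_mgdl = y + 25)
  dg2 <- suppressWarnings(regression_diagnostics(shifted))
  expect_equal(dg2$slope, 1)
  expect_equal(dg2$intercept, 25)

  # low-noise synthetic run: slope within 1 +/- 3 SE (coverage check)
  withr::with_seed(36, {
    ok <- vapply(1:20, function(i) {
      pred <- y + rnorm(20, sd = 5)
      dgi <- regression_diagnostics(tibble::tibble(glucose_mgdl = y,
                                                   predicted_mgdl = pred))
      abs(dgi$slope - 1) < 3 * dgi$slope_se
    }, logical(1))
  })
  expect_gte(mean(ok), 0.9)
})

test_that("label randomization permutes reproducibly and preserves the multiset", {
  d <- table1_design()
  ds <- simulate_calibration_dataset(d[1:10, ], "laser", seed = 2)
  r1 <- randomize_labels(ds, seed = 42)
  r2 <- randomize_labels(ds, seed = 42)
  expect_identical(r1, r2)
  expect_setequal(r1$glucose_mgdl, ds$glucose_mgdl)
  expect_equal(sort(r1$glucose_mgdl), sort(ds$glucose_mgdl))
  # spectra untouched
  expect_equal(r1[wl_cols(r1)], ds[wl_cols(ds)])
})

test_that("tidy and glance methods expose model structure", {
  withr::with_seed(37, {
    x <- matrix(rnorm(100), 10, 10)
    y <- rnorm(10)
  })
  data <- cal_tbl(x, y)
  fit <- fit_pls(data, n_factors = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_named(td, c("wavelength_nm", "coefficient"))
  expect_equal(glance(fit)$n_factors, 3)
  cv <- lopo_cv(data, n_factors = 2)
  expect_named(tidy(cv), c("phantom_id", "glucose_mgdl", "predicted_mgdl"))
  expect_true(all(c("secv_mgdl", "slope", "r_squared") %in% names(glance(cv))))
})
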