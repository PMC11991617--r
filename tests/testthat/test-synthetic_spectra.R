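test_that("pure water limit returns the water baseline", {
  lib <- absorptivity_library()
  grid <- wavelength_grid(60)
  blank <- list(glucose_mgdl = 0, beads_mgdl = 0, triton_mgdl = 0,
                saline_mgdl = 0, germall_mgdl = 0)
  a <- simulate_absorbance(blank, grid, lib)
  expect_equal(a$absorbance_au, absorptivity(lib, "water", grid))
})

test_that("absorbance is affine in glucose at fixed matrix", {
  lib <- absorptivity_library()
  grid <- wavelength_grid(80)
  at <- function(c) simulate_absorbance(
    list(glucose_mgdl = c, beads_mgdl = 1700, triton_mgdl = 800,
         saline_mgdl = 966, germall_mgdl = 100), grid, lib)$absorbance_au
  a0 <- at(0)
  expect_equal(at(500) - a0, 2 * (at(250) - a0), tolerance = 1e-12)
  # noiseless linearity: R^2 of a line through A(band center) vs c is 1
  cc <- c(0, 100, 200, 300, 400, 500)
  idx <- which.min(abs(grid - 2100))
  vals <- vapply(cc, function(c) at(c)[idx], double(1))
  fit <- lm(vals ~ cc)
  expect_lt(max(abs(residuals(fit))), 1e-12 * max(abs(vals)))
})

test_that("glucose band contribution equals absorptivity times concentration", {
  lib <- glucose_only_library()
  grid <- wavelength_grid(112)
  a500 <- simulate_absorbance(list(glucose_mgdl = 500), grid, lib)
  a0 <- simulate_absorbance(list(glucose_mgdl = 0), grid, lib)
  expect_equal(a500$absorbance_au - a0$absorbance_au,
               absorptivity(lib, "glucose", grid) * 500)
})

test_that("library span is enforced and concentrations validated", {
  lib <- absorptivity_library(range_nm = c(1400, 2400))
  expect_error(simulate_absorbance(list(glucose_mgdl = 0), wavelength_grid(10, 1350, 2450), lib),
               "outside the library range")
  expect_error(simulate_absorbance(list(glucose_mgdl = -5), wavelength_grid(10)),
               ">= 0")
})

test_that("single-beam conversion inverts the absorbance transform", {
  a <- tibble::tibble(wavelength_nm = wavelength_grid(20),
                      absorbance_au = c(0, 1, seq(0.1, 1.5, length.out = 18)))
  sb <- absorbance_to_single_beam(a, i0 = 1000)
  expect_equal(sb$intensity[1], 1000)  # A = 0
  expect_equal(sb$intensity[2], 100)   # one decade
  back <- to_absorbance(sb, reference = 1000)
  expect_equal(back$absorbance_au, a$absorbance_au, tolerance = 1e-12)
})

test_that("time series scan count, determinism and noiseless stability", {
  rec <- table1_design()[1, ]
  s <- simulate_time_series(rec, wavelength_grid(20), duration_s = 120,
                            scan_rate = 8.33)
  expect_equal(nrow(s), floor(120 * 8.33))  # 999 under the floor convention
  m <- spectra_matrix(s)
  expect_true(all(abs(sweep(m, 2, m[1, ])) < 1e-12))  # no noise -> identical scans

  s1 <- simulate_time_series(rec, wavelength_grid(20), duration_s = 5,
                             scan_rate = 4, noise_rms_uau = 300, seed = 7)
  s2 <- simulate_time_series(rec, wavelength_grid(20), duration_s = 5,
                             scan_rate = 4, noise_rms_uau = 300, seed = 7)
  expect_identical(s1, s2)
  expect_error(simulate_time_series(rec, wavelength_grid(20), duration_s = 5,
                                    scan_rate = 4, noise_rms_uau = -1), ">=")
  expect_error(simulate_time_series(rec, wavelength_grid(20), duration_s = 0.1,
                                    scan_rate = 4), ">= 2")
})

test_that("modulation cycle has the documented on/off structure", {
  sb <- tibble::tibble(wavelength_nm = c(1400, 1500, 1600), intensity = c(100, 50, 25))
  cyc <- simulate_modulation_cycle(sb, dark_level = 5)
  expect_equal(unique(cyc$value[cyc$laser_index == -1]), 5)
  expect_equal(unique(cyc$value[cyc$laser_index == 1]), 105)
  # lasers fire in order of increasing wavelength
  on_first <- dplyr::summarise(dplyr::filter(cyc, laser_index > 0),
                               t = min(time_us), .by = laser_index)
  expect_equal(on_first$laser_index[order(on_first$t)], 1:3)
  expect_error(simulate_modulation_cycle(sb, sample_interval_us = 7), "divide")
  expect_error(simulate_modulation_cycle(sb, dark_us = 100), "200 us")
})

test_that("demodulated intensities converge to the input as noise vanishes", {
  sb <- tibble::tibble(wavelength_nm = wavelength_grid(10), intensity = seq(100, 10, length.out = 10))
  err <- vapply(c(2, 0.2, 0.02), function(sd) {
    cyc <- simulate_modulation_cycle(sb, noise_sd = sd, seed = 3)
    max(abs(demodulate(cyc)$intensity - sb$intensity))
  }, double(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("calibration dataset generator is seeded and noise-scaled correctly", {
  d <- table1_design()[1:6, ]
  ds1 <- simulate_calibration_dataset(d, "laser", seed = 9)
  ds2 <- simulate_calibration_dataset(d, "laser", seed = 9)
  expect_identical(ds1, ds2)

  # with all systematic variation off, the residual around the noiseless
  # spectrum is white with RMS sigma_scan / sqrt(n_scans)
  lib <- absorptivity_library()
  grid <- wavelength_grid()
  prof <- instrument_profile("laser")
  ds <- simulate_calibration_dataset(d, prof, grid, lib,
                                     variation = no_variation(), seed = 4)
  eff <- nirphantom:::profile_effective(prof)
  resid <- vapply(seq_len(nrow(d)), function(i) {
    truth <- simulate_absorbance(d[i, ], grid, lib)$absorbance_au
    stats::sd(as.numeric(ds[i, wl_cols(ds)]) - truth)
  }, double(1))
  expected <- eff$sigma_uau * 1e-6 / sqrt(eff$n_scans)
  expect_equal(mean(resid), expected, tolerance = 0.1)
  expect_equal(ds$n_scans[1], floor(120 * 15.15 / 2))
})
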