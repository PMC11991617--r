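# A deliberately small configuration so the end-to-end drivers stay fast:
# short acquisitions and a coarse grid, with the design and noise levels
# unchanged.
tiny_config <- function(seed = 4) {
  study_config(
    seed = seed,
    generator = list(grid_n = 40),
    profiles = list(
      ft = utils::modifyList(instrument_profile("ft"), list(duration_s = 3)),
      laser = utils::modifyList(instrument_profile("laser"),
                                list(duration_s = 10, trim_s = c(2, 8)))
    ),
    pls = list(factors_max = 6, min_width_nm = 400, width_step_nm = 400,
               start_step_nm = 300)
  )
}

test_that("configuration validates, serializes and round-trips", {
  cfg <- study_config(seed = 3)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$design$glucose_levels, design_levels()$glucose)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, tmp)
  cfg2 <- read_study_config(tmp)
  expect_equal(unclass(cfg), unclass(cfg2))

  writeLines(c("seed: 1", "bogus_section:", "  a: 1"), tmp)
  expect_error(read_study_config(tmp), "bogus_section")
  expect_error(study_config(pls = list(factors_max = 0)), "factors_max")
})

test_that("spectra CSV dialect round-trips with its sidecar", {
  s <- make_spectra(matrix(rnorm(20, 1000), 4), wavelengths = wavelength_grid(5),
                    phantom_id = "P07")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, tmp, metadata = list(profile = "laser"))
  back <- read_spectra_csv(tmp)
  expect_equal(back$phantom_id, rep("P07", 4))
  expect_equal(spectra_matrix(back), spectra_matrix(s))
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$profile, "laser")
})

test_that("the simulation driver writes a complete, reproducible study", {
  cfg <- tiny_config()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res <- run_simulation(cfg, dir1)
  expect_equal(nrow(res$design), 49)
  expect_true(file.exists(file.path(dir1, "design.csv")))
  expect_true(file.exists(file.path(dir1, "recipes.csv")))
  expect_length(list.files(file.path(dir1, "spectra", "ft")), 2 * 49)  # csv + sidecar
  expect_length(list.files(file.path(dir1, "spectra", "laser")), 2 * 49)
  expect_length(list.files(file.path(dir1, "cycles")), 1)

  run_simulation(cfg, dir2)
  for (f in c("design.csv", "spectra/laser/P01.csv", "spectra/ft/P25.csv",
              "cycles/cycle_P01.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("the benchmark driver reports medians per profile with the set ratio", {
  cfg <- tiny_config()
  d <- build_design()
  lib <- absorptivity_library()
  sub <- d[c(1, 25), ]
  mk <- function(profile) {
    dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
      simulate_time_series(sub[i, ], nirphantom:::config_grid(cfg), lib,
                           duration_s = 30, scan_rate = profile$scan_rate,
                           noise_rms_uau = profile$noise_rms_uau,
                           seed = 100 + i)
    }))
  }
  bench_ft <- run_benchmark(cfg, "ft", spectra = mk(cfg$profiles$ft))
  bench_laser <- run_benchmark(cfg, "laser", spectra = mk(cfg$profiles$laser))
  # generator-set noise gap: line medians 667.2 vs 327.8 uAU
  expect_equal(bench_laser$summary$median_uau, 667.2, tolerance = 0.06)
  expect_equal(bench_ft$summary$median_uau, 327.8, tolerance = 0.06)
  expect_equal(bench_laser$summary$median_uau / bench_ft$summary$median_uau,
               667.2 / 327.8, tolerance = 0.1)
  expect_true(all(c("median_uau", "snr_median", "median_one_minute_uau")
                  %in% names(bench_ft$summary)))

  # zero-noise input benchmarks to exactly zero
  quiet <- utils::modifyList(cfg$profiles$ft, list(noise_rms_uau = 0))
  bench0 <- run_benchmark(cfg, "ft", spectra = mk(quiet))
  expect_equal(bench0$summary$median_uau, 0)
})

test_that("the full study driver chains all stages under one output tree", {
  cfg <- tiny_config()
  out <- withr::local_tempdir()
  res <- run_full_study(cfg, out)
  expect_named(res, c("simulation", "benchmark", "calibration", "randomized"))
  expect_true(file.exists(file.path(out, "noise_report_laser.json")))
  expect_true(file.exists(file.path(out, "pls_report_laser.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # correct labels on low-noise synthetic data: slope near 1 (consistency)
  expect_equal(res$calibration$ft$diagnostics$slope, 1, tolerance = 0.05)
  # the report records the generator parameters used
  rep <- jsonlite::read_json(file.path(out, "pls_report_laser.json"))
  expect_equal(rep$generator$grid_n, 40)
  # randomized labels destroy the calibration
  expect_gt(res$randomized$cv$secv_mgdl, 5 * res$calibration$ft$cv$secv_mgdl)
})

test_that("plot builders return ggplot objects", {
  wl <- wavelength_grid(30)
  line <- detrend(tibble::tibble(wavelength_nm = wl,
                                 value_au = 1e-4 * sin(wl / 100)))
  expect_s3_class(plot_hundred_percent_lines(line), "gg")
  expect_s3_class(plot_hundred_percent_lines(line, residuals = TRUE), "gg")

  per_line <- tibble::tibble(phantom_id = rep(c("P01", "P02"), each = 5),
                             rms_uau = runif(10, 300, 700))
  expect_s3_class(plot_rms_boxplot(per_line), "gg")

  ds <- simulate_calibration_dataset(table1_design(), "laser", seed = 5)
  cv <- lopo_cv(ds, n_factors = 4)
  expect_s3_class(autoplot(cv), "gg")
  curve <- secv_curve(ds, factors = c(1, 2, 4))
  expect_s3_class(plot_secv_curve(curve), "gg")
  gs <- grid_search(ds, min_width_nm = 500, width_step_nm = 600,
                    start_step_nm = 600, factors = c(2, 4))
  expect_s3_class(autoplot(gs), "gg")
})
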