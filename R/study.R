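# Study configuration and end-to-end drivers: simulate a synthetic two-
# instrument phantom study, benchmark its noise, and run the PLS calibration
# analyses with randomization and noise-injection variants.

#' Build a study configuration
#'
#' Collects every tunable of the synthetic study in one (YAML-serializable)
#' object: design levels, generator parameters, per-instrument acquisition
#' profiles, benchmark options and PLS grid-search options. Defaults
#' reproduce the benchmarked study conditions: a 49-phantom 7x7 design, a
#' 112-wavelength grid over 1350-2450 nm, a low-noise "ft" profile (2 min at
#' 8.33 scans/s) and a high-noise "laser" profile (7 min at 15.15 scans/s,
#' pairwise averaging, 2.5 min trims).
#'
#' @param seed Master seed; all per-phantom seeds derive from it.
#' @param design,generator,profiles,benchmark,pls Named lists overriding
#'   individual defaults within each section.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, design = list(), generator = list(),
                         profiles = list(), benchmark = list(), pls = list()) {
  merge_sec <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    seed = seed,
    design = merge_sec(list(
      glucose_levels = design_levels()$glucose,
      bead_levels = design_levels()$beads,
      triton_mgdl = 800, saline_mgdl = 966, germall_mgdl = 100
    ), design),
    generator = merge_sec(list(
      grid_n = 112, grid_min_nm = 1350, grid_max_nm = 2450,
      temperature_c = 32, temperature_jitter_c = 0.1, i0_peak = 1000,
      n_cycle_examples = 1
    ), generator),
    # NULL profile fields (e.g. no trim window) are dropped so the config
    # round-trips through YAML unchanged
    profiles = lapply(
      merge_sec(list(ft = instrument_profile("ft"),
                     laser = instrument_profile("laser")), profiles),
      function(p) p[!vapply(p, is.null, logical(1))]
    ),
    benchmark = merge_sec(list(detrend_order = 2, regressor = "wavelength"),
                          benchmark),
    pls = merge_sec(list(factors_max = 20, min_width_nm = 50,
                         width_step_nm = 50, start_step_nm = 50), pls)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  for (key in c("seed")) check_number(cfg[[key]], key)
  with(cfg$generator, {
    check_number(grid_n, "grid_n", min = 2)
    check_number(temperature_jitter_c, "temperature_jitter_c", min = 0)
  })
  for (p in cfg$profiles) {
    check_number(p$scan_rate, "scan_rate", min = 0, strict_min = TRUE)
    check_number(p$noise_rms_uau, "noise_rms_uau", min = 0)
  }
  check_number(cfg$pls$factors_max, "factors_max", min = 1)
  check_number(cfg$benchmark$detrend_order, "detrend_order", min = 0)
  invisible(cfg)
}

#' Read or write a study configuration as YAML
#'
#' @param path File path.
#' @param config A `study_config`.
#' @return `read_study_config()` returns the validated `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), c("seed", "design", "generator", "profiles",
                                 "benchmark", "pls"))
  if (length(extra)) {
    abort(paste0("Unknown configuration keys: ", paste(extra, collapse = ", ")))
  }
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_grid <- function(cfg) {
  wavelength_grid(cfg$generator$grid_n, cfg$generator$grid_min_nm,
                  cfg$generator$grid_max_nm)
}

phantom_seed <- function(master, i, salt = 0) {
  (as.integer(master) * 7919L + as.integer(salt) * 104729L + as.integer(i)) %%
    2147483629L
}

#' Write / read the wide spectra CSV dialect
#'
#' One row per scan, first column `timestamp_s`, remaining columns named with
#' the wavelength in nm. A JSON sidecar (`<path>.json`) records phantom id,
#' scan rate and any generator parameters supplied.
#'
#' @param spectra A wide spectra tibble for one phantom.
#' @param path CSV path.
#' @param metadata Named list merged into the sidecar.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns the spectra tibble.
#' @export
write_spectra_csv <- function(spectra, path, metadata = list()) {
  readr::write_csv(dplyr::select(spectra, -"phantom_id"), path)
  meta <- c(list(phantom_id = spectra$phantom_id[1],
                 scan_rate = if (nrow(spectra) > 1) scan_rate(spectra) else NA),
            metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  pid <- if (file.exists(sidecar)) jsonlite::read_json(sidecar)$phantom_id else NA_character_
  dplyr::mutate(df, phantom_id = as.character(pid), .before = 1)
}

#' Apply a profile's harmonization chain to a raw simulated series
#'
#' Laser-profile series get pairwise scan averaging and duration trimming;
#' ft-profile series (simulated on their native 391-point grid) are resampled
#' onto the target grid. Output series from both profiles are directly
#' comparable single-beam spectra on the same grid.
#'
#' @param spectra A wide single-beam spectra tibble.
#' @param profile An [instrument_profile()] (or name).
#' @param target_grid Target wavelength grid, nm.
#' @return The harmonized spectra tibble.
#' @export
preprocess_series <- function(spectra, profile, target_grid) {
  if (is.character(profile)) profile <- instrument_profile(profile)
  out <- spectra
  if (isTRUE(profile$pairwise_average)) out <- pairwise_average(out)
  if (!is.null(profile$trim_s)) {
    out <- trim_to_window(out, profile$trim_s[1], profile$trim_s[2])
  }
  if (!isTRUE(all.equal(wl_values(out), target_grid))) {
    out <- resample_to_grid(out, target_grid)
  }
  out
}

simulate_profile_series <- function(design, profile, cfg, lib, phantom_rows = NULL) {
  grid <- config_grid(cfg)
  native <- if (!is.null(profile$native_points)) {
    wavelength_grid(profile$native_points, profile$native_range_nm[1],
                    profile$native_range_nm[2])
  } else grid
  rows <- phantom_rows %||% seq_len(nrow(design))
  purrr::map(rows, function(i) {
    simulate_time_series(
      design[i, ], grid = native, lib = lib,
      duration_s = profile$duration_s, scan_rate = profile$scan_rate,
      noise_rms_uau = profile$noise_rms_uau,
      temperature_c = cfg$generator$temperature_c,
      i0 = reference_intensity(native, cfg$generator$i0_peak),
      seed = phantom_seed(cfg$seed, i, salt = match(profile$name, names(cfg$profiles)))
    )
  }) |>
    dplyr::bind_rows()
}

#' Simulate and write a complete synthetic study
#'
#' Writes the design and recipe CSVs, raw spectra CSVs per phantom for both
#' instrument profiles, example modulation-cycle CSVs for the laser profile,
#' and a manifest JSON recording the seeds and generator parameters. The same
#' configuration always produces byte-identical outputs.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param lib An [absorptivity_library()].
#' @return Invisibly, a list with the design and the manifest.
#' @export
run_simulation <- function(config, out_dir, lib = absorptivity_library()) {
  validate_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- build_design(config$design$glucose_levels, config$design$bead_levels,
                         config$design$triton_mgdl, config$design$saline_mgdl,
                         config$design$germall_mgdl)
  readr::write_csv(design, file.path(out_dir, "design.csv"))
  readr::write_csv(phantom_recipes(design), file.path(out_dir, "recipes.csv"))

  for (pname in names(config$profiles)) {
    profile <- config$profiles[[pname]]
    pdir <- file.path(out_dir, "spectra", pname)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(design))) {
      s <- simulate_profile_series(design, profile, config, lib, phantom_rows = i)
      write_spectra_csv(
        s, file.path(pdir, paste0(design$phantom_id[i], ".csv")),
        metadata = list(profile = pname,
                        seed = phantom_seed(config$seed, i,
                                            salt = match(pname, names(config$profiles))),
                        noise_rms_uau = profile$noise_rms_uau)
      )
    }
  }

  n_cyc <- min(config$generator$n_cycle_examples, nrow(design))
  if (n_cyc > 0) {
    cdir <- file.path(out_dir, "cycles")
    dir.create(cdir, showWarnings = FALSE)
    grid <- config_grid(config)
    for (i in seq_len(n_cyc)) {
      a <- simulate_absorbance(design[i, ], grid, lib,
                               config$generator$temperature_c)
      sb <- absorbance_to_single_beam(a, reference_intensity(grid, config$generator$i0_peak))
      cyc <- simulate_modulation_cycle(sb, seed = phantom_seed(config$seed, i, salt = 99))
      readr::write_csv(cyc, file.path(cdir, paste0("cycle_", design$phantom_id[i], ".csv")))
    }
  }

  manifest <- list(seed = config$seed, n_phantoms = nrow(design),
                   profiles = names(config$profiles),
                   grid = list(n = config$generator$grid_n,
                               min_nm = config$generator$grid_min_nm,
                               max_nm = config$generator$grid_max_nm))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, manifest = manifest))
}

#' Benchmark the 100% line noise of a simulated study
#'
#' Reads (or accepts) the raw spectra of one profile, harmonizes them, forms
#' per-phantom 100% lines from consecutive scan pairs and reports per-line
#' RMS values with medians, quartiles, SNRs and one-minute scaled medians.
#'
#' @param config A [study_config()].
#' @param profile Profile name ("ft" or "laser").
#' @param spectra_dir Directory written by [run_simulation()]; ignored when
#'   `spectra` is supplied.
#' @param spectra Optional pre-loaded raw spectra tibble for the profile.
#' @param out_dir Optional directory for `noise_report.json` and
#'   `per_line_rms.csv`.
#' @return A list with `per_line`, `summary` (overall), `by_phantom`.
#' @export
run_benchmark <- function(config, profile, spectra_dir = NULL, spectra = NULL,
                          out_dir = NULL) {
  prof <- config$profiles[[profile]]
  if (is.null(prof)) abort(sprintf("Unknown profile '%s'.", profile))
  if (is.null(spectra)) {
    paths <- list.files(file.path(spectra_dir, "spectra", profile),
                        pattern = "\\.csv$", full.names = TRUE)
    if (!length(paths)) abort("No spectra CSVs found for this profile.")
    spectra <- dplyr::bind_rows(purrr::map(paths, read_spectra_csv))
  }
  grid <- config_grid(config)
  processed <- preprocess_series(spectra, prof, grid)
  per_line <- benchmark_spectra(processed, k = config$benchmark$detrend_order,
                                regressor = config$benchmark$regressor)
  eff_rate <- profile_effective(prof)$rate
  overall <- rms_summary(per_line, n_scans_one_minute = eff_rate * 60)
  by_phantom <- rms_summary(per_line, by_phantom = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_line, file.path(out_dir, paste0("per_line_rms_", profile, ".csv")))
    jsonlite::write_json(
      list(profile = profile, summary = overall, by_phantom = by_phantom,
           detrend_order = config$benchmark$detrend_order),
      file.path(out_dir, paste0("noise_report_", profile, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(per_line = per_line, summary = overall, by_phantom = by_phantom)
}

#' Run the PLS calibration analysis of a simulated study
#'
#' Harmonizes the raw spectra, optionally injects calibrated noise
#' (matching a target median 100% line RMS), averages to one absorbance
#' spectrum per phantom, optionally randomizes the glucose labels, and runs
#' the wavelength-window grid search with leave-one-phantom-out SECV,
#' reporting the optimum model, its regression diagnostics and the
#' SECV-vs-factor curve at the optimal window.
#'
#' @param config A [study_config()].
#' @param profile Profile name.
#' @param design The design tibble (or NULL to read `design.csv` from
#'   `spectra_dir`).
#' @param spectra_dir,spectra As in [run_benchmark()].
#' @param randomize_labels Permute glucose labels before modeling.
#' @param inject_noise_to Optional target median RMS (uAU) for noise
#'   injection prior to averaging.
#' @param out_dir Optional output directory for the report JSON/CSVs.
#' @return A list with `dataset`, `search` (`pls_grid_search`), `cv`
#'   (optimal-model `lopo_cv`), `diagnostics`, `secv_curve`, and
#'   `injection` (when noise was injected).
#' @export
run_calibration <- function(config, profile, design = NULL, spectra_dir = NULL,
                            spectra = NULL, randomize_labels = FALSE,
                            inject_noise_to = NULL, out_dir = NULL) {
  prof <- config$profiles[[profile]]
  if (is.null(prof)) abort(sprintf("Unknown profile '%s'.", profile))
  if (is.null(spectra)) {
    paths <- list.files(file.path(spectra_dir, "spectra", profile),
                        pattern = "\\.csv$", full.names = TRUE)
    if (!length(paths)) abort("No spectra CSVs found for this profile.")
    spectra <- dplyr::bind_rows(purrr::map(paths, read_spectra_csv))
  }
  if (is.null(design)) {
    design <- readr::read_csv(file.path(spectra_dir, "design.csv"),
                              show_col_types = FALSE)
  }
  grid <- config_grid(config)
  processed <- preprocess_series(spectra, prof, grid)

  injection <- NULL
  if (!is.null(inject_noise_to)) {
    injection <- calibrate_injection_noise(processed, inject_noise_to,
                                           k = config$benchmark$detrend_order,
                                           seed = phantom_seed(config$seed, 1, salt = 7))
    processed <- injection$noisy
    injection$noisy <- NULL
  }

  dataset <- processed |>
    to_absorbance() |>
    phantom_mean_spectrum() |>
    dplyr::inner_join(dplyr::select(design, "phantom_id", "glucose_mgdl",
                                    "beads_mgdl"),
                      by = "phantom_id") |>
    dplyr::relocate("glucose_mgdl", "beads_mgdl", .after = "phantom_id")
  if (randomize_labels) {
    dataset <- randomize_labels(dataset, seed = phantom_seed(config$seed, 2, salt = 11))
  }

  search <- grid_search(dataset,
                        min_width_nm = config$pls$min_width_nm,
                        width_step_nm = config$pls$width_step_nm,
                        start_step_nm = config$pls$start_step_nm,
                        factors = seq_len(config$pls$factors_max))
  opt <- search$optimum
  cv <- lopo_cv(dataset, n_factors = opt$n_factors,
                window = c(opt$start_nm, opt$end_nm))
  diagnostics <- regression_diagnostics(cv)
  curve <- secv_curve(dataset, factors = seq_len(config$pls$factors_max),
                      window = c(opt$start_nm, opt$end_nm))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- paste0(profile, if (randomize_labels) "_randomized" else "",
                  if (!is.null(inject_noise_to)) "_injected" else "")
    readr::write_csv(cv$predictions, file.path(out_dir, paste0("predictions_", tag, ".csv")))
    readr::write_csv(search$surface, file.path(out_dir, paste0("secv_surface_", tag, ".csv")))
    jsonlite::write_json(
      list(profile = profile, randomized = randomize_labels,
           injected_to_uau = inject_noise_to,
           optimum = opt, diagnostics = diagnostics, secv_curve = curve,
           generator = config$generator),
      file.path(out_dir, paste0("pls_report_", tag, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(dataset = dataset, search = search, cv = cv, diagnostics = diagnostics,
       secv_curve = curve, injection = injection)
}

#' Run the full synthetic study end to end
#'
#' Chains [run_simulation()], [run_benchmark()] for both profiles, and
#' [run_calibration()] (correct and randomized labels) under one manifest in
#' `out_dir`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory.
#' @param lib An [absorptivity_library()].
#' @return Invisibly, a list of the stage results.
#' @export
run_full_study <- function(config, out_dir, lib = absorptivity_library()) {
  sim <- run_simulation(config, out_dir, lib = lib)
  bench <- purrr::map(names(config$profiles), function(p) {
    run_benchmark(config, p, spectra_dir = out_dir, out_dir = out_dir)
  }) |> setNames(names(config$profiles))
  calib <- purrr::map(names(config$profiles), function(p) {
    run_calibration(config, p, design = sim$design, spectra_dir = out_dir,
                    out_dir = out_dir)
  }) |> setNames(names(config$profiles))
  random <- run_calibration(config, names(config$profiles)[1],
                            design = sim$design, spectra_dir = out_dir,
                            randomize_labels = TRUE, out_dir = out_dir)
  invisible(list(simulation = sim, benchmark = bench, calibration = calib,
                 randomized = random))
}
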