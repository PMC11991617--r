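# Forward simulation of single-beam spectra, spectral time series and raw
# pulsed-laser modulation cycles.

#' Reference (source) intensity profile
#'
#' A smooth, broad detector-count profile standing in for the unknown lamp /
#' laser power envelope; any common reference cancels in 100% lines and is
#' absorbed by PLS centering.
#'
#' @param grid Wavelength grid, nm.
#' @param peak Peak detector counts.
#' @return Numeric vector of intensities (> 0), one per wavelength.
#' @export
reference_intensity <- function(grid, peak = 1000) {
  peak * (1 - 0.3 * ((grid - 1900) / 550)^2 * 0.5)
}

#' Convert absorbance to a single-beam spectrum
#'
#' I = I0 * 10^(-A); the inverse of the absorbance transform, so
#' [to_absorbance()] recovers A exactly.
#'
#' @param absorbance Tibble with `wavelength_nm` and `absorbance_au`.
#' @param i0 Reference intensity: scalar or one value per wavelength.
#' @return A tibble with `wavelength_nm` and `intensity`.
#' @export
absorbance_to_single_beam <- function(absorbance, i0 = 1000) {
  check_number(i0, "i0", min = 0, strict_min = TRUE)
  tibble::tibble(
    wavelength_nm = absorbance$wavelength_nm,
    intensity = i0 * 10^(-absorbance$absorbance_au)
  )
}

#' Simulate a single-beam spectral time series for one phantom
#'
#' Generates `floor(duration_s * scan_rate)` scans. Each scan's absorbance is
#' the phantom's noiseless spectrum plus optional linear drift, a temperature
#' ramp acting through the library's dA/dT curve, and independent white noise
#' of the given absorbance-equivalent RMS; intensities are then formed as
#' I0 * 10^(-A).
#'
#' @param recipe One design row (see [simulate_absorbance()]).
#' @param grid Wavelength grid, nm.
#' @param lib An [absorptivity_library()].
#' @param duration_s Acquisition duration, s; `duration_s * scan_rate >= 2`.
#' @param scan_rate Scans per second.
#' @param noise_rms_uau Per-scan, per-wavelength white noise RMS in
#'   micro-absorbance units (uAU); must be >= 0.
#' @param drift_au_per_min Linear absorbance drift, AU/min.
#' @param temp_drift_c_per_min Temperature ramp, degC/min.
#' @param temperature_c Starting temperature, degC.
#' @param i0 Reference intensity (scalar or per wavelength).
#' @param seed Optional integer seed; the same seed gives a bit-identical
#'   series without touching the global RNG stream.
#' @return A wide spectra tibble: `phantom_id`, `timestamp_s`, then one
#'   intensity column per wavelength.
#' @export
simulate_time_series <- function(recipe, grid = wavelength_grid(),
                                 lib = absorptivity_library(),
                                 duration_s, scan_rate,
                                 noise_rms_uau = 0, drift_au_per_min = 0,
                                 temp_drift_c_per_min = 0,
                                 temperature_c = lib$t_ref_c,
                                 i0 = 1000, seed = NULL) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(scan_rate, "scan_rate", min = 0, strict_min = TRUE)
  check_number(noise_rms_uau, "noise_rms_uau", min = 0)
  n <- floor(duration_s * scan_rate)
  if (n < 2) abort("`duration_s * scan_rate` must be >= 2 scans.")

  base <- simulate_absorbance(recipe, grid, lib, temperature_c)$absorbance_au
  dadt <- eval_bands(lib$dAdT_bands, grid)
  ts <- (seq_len(n) - 1) / scan_rate
  sigma <- noise_rms_uau * 1e-6

  a <- matrix(base, nrow = n, ncol = length(grid), byrow = TRUE)
  a <- a + (ts / 60) %o% rep(drift_au_per_min, length(grid))
  a <- a + (temp_drift_c_per_min * ts / 60) %o% dadt
  if (sigma > 0) {
    a <- a + with_seed_if(seed, matrix(rnorm(n * length(grid), sd = sigma),
                                       nrow = n))
  }
  intens <- sweep(10^(-a), 2, rep_len(i0, length(grid)), `*`)
  pid <- recipe[["phantom_id"]] %||% NA_character_
  new_spectra_tbl(intens, grid, ts, phantom_id = as.character(pid))
}

#' Simulate the prototype's pulsed-laser modulation cycle
#'
#' Emulates the raw detector stream of the laser prototype: lasers fire one
#' after another in order of increasing wavelength, each pulse lasting
#' `pulse_us` with `dark_us` of dark signal between pulses (so every pulse has
#' dark signal on both sides). On-samples have mean `dark_level + intensity`;
#' dark samples have mean `dark_level`.
#'
#' @param spectrum Single-beam tibble (`wavelength_nm`, `intensity`).
#' @param dark_level Dark (laser-off) detector level.
#' @param pulse_us Laser on-time per laser, microseconds.
#' @param dark_us Dark time between pulses, microseconds; must be >= 200 so
#'   that the demodulation windows (100 us on each side) exist.
#' @param sample_interval_us Detector sampling interval; must divide
#'   `pulse_us`, `dark_us` and 100 us exactly.
#' @param noise_sd Gaussian detector noise SD (detector units).
#' @param seed Optional seed for the noise.
#' @return A tibble with `time_us`, `laser_index` (1-based in wavelength
#'   order; -1 for dark samples) and `value`, with the wavelength lookup in
#'   attribute `"wavelength_nm"`.
#' @export
simulate_modulation_cycle <- function(spectrum, dark_level = 5, pulse_us = 200,
                                      dark_us = 300, sample_interval_us = 10,
                                      noise_sd = 0, seed = NULL) {
  for (seg in c(pulse = pulse_us, dark = dark_us, window = 100)) {
    if (seg %% sample_interval_us != 0) {
      abort(sprintf("`sample_interval_us` (%g) must divide pulse, dark and 100 us segment durations.",
                    sample_interval_us))
    }
  }
  if (dark_us < 200) abort("`dark_us` must be >= 200 us to fit both 100 us demodulation windows.")
  check_number(noise_sd, "noise_sd", min = 0)

  ord <- order(spectrum$wavelength_nm)
  wl <- spectrum$wavelength_nm[ord]
  intensity <- spectrum$intensity[ord]
  n_on <- pulse_us / sample_interval_us
  n_dark <- dark_us / sample_interval_us

  idx <- c(rep(-1L, n_dark),
           unlist(lapply(seq_along(wl), function(i) c(rep(i, n_on), rep(-1L, n_dark)))))
  mean_val <- dark_level + ifelse(idx == -1L, 0, intensity[pmax(idx, 1L)])
  val <- if (noise_sd > 0) {
    mean_val + with_seed_if(seed, rnorm(length(idx), sd = noise_sd))
  } else mean_val

  out <- tibble::tibble(
    time_us = (seq_along(idx) - 1) * sample_interval_us,
    laser_index = idx,
    value = val
  )
  attr(out, "wavelength_nm") <- wl
  attr(out, "sample_interval_us") <- sample_interval_us
  out
}

#' Instrument acquisition profiles
#'
#' Acquisition parameters for the two emulated instruments. The "ft"
#' (Fourier-transform) profile collects 2 min at 8.33 scans/s on a native
#' 391-point grid with per-scan absorbance noise 327.8/sqrt(2) uAU, so its
#' 100% lines carry 327.8 uAU RMS. The "laser" prototype profile collects
#' 7 min at 15.15 scans/s with per-raw-scan noise 667.2 uAU; pairwise scan
#' averaging (rate 7.58/s) and trimming of the first and last 2.5 min leave a
#' two-minute segment whose 100% lines carry 667.2 uAU RMS.
#'
#' @param name "ft" or "laser".
#' @return A list of profile fields: `name`, `scan_rate`, `duration_s`,
#'   `noise_rms_uau`, `pairwise_average`, `trim_s` (NULL or c(start, end)),
#'   `native_points` (NULL to use the target grid), `native_range_nm`.
#' @export
instrument_profile <- function(name = c("laser", "ft")) {
  name <- match.arg(name)
  if (name == "ft") {
    list(name = "ft", scan_rate = 8.33, duration_s = 120,
         noise_rms_uau = 327.8 / sqrt(2), pairwise_average = FALSE,
         trim_s = NULL, native_points = 391, native_range_nm = c(1300, 2500))
  } else {
    list(name = "laser", scan_rate = 15.15, duration_s = 420,
         noise_rms_uau = 667.2, pairwise_average = TRUE,
         trim_s = c(150, 270), native_points = NULL, native_range_nm = NULL)
  }
}

# Effective number of processed (possibly pairwise-averaged, trimmed) scans
# and per-processed-scan noise RMS for a profile.
profile_effective <- function(profile) {
  rate <- profile$scan_rate
  sigma <- profile$noise_rms_uau
  if (isTRUE(profile$pairwise_average)) {
    rate <- rate / 2
    sigma <- sigma / sqrt(2)
  }
  dur <- if (!is.null(profile$trim_s)) diff(profile$trim_s) else profile$duration_s
  list(n_scans = floor(dur * rate), sigma_uau = sigma, rate = rate)
}

#' Per-phantom measurement variation model
#'
#' Diffuse-reflectance measurements carry phantom-to-phantom systematic
#' variation beyond composition: repositioning of the sample-to-instrument
#' interface shifts the baseline offset, slope and curvature; effective
#' pathlength differences rescale the whole absorbance spectrum; and the
#' sample temperature wanders slightly around the setpoint. These smooth,
#' low-order effects dominate the between-phantom spectral variance in real
#' data, so the calibration generator draws one realization of each per
#' phantom.
#'
#' @param offset_sd_au SD of the per-phantom baseline offset, AU.
#' @param slope_sd_au_per_nm SD of the baseline slope, AU/nm (zero at the
#'   grid center).
#' @param curvature_sd_au SD of the baseline curvature, AU at the grid edges.
#' @param pathlength_scale_sd Relative SD of the whole-spectrum scaling.
#' @param temperature_jitter_c SD of the per-phantom temperature offset, degC.
#' @param baseline_wander_sd_au SD of the smooth per-phantom baseline wander
#'   at each wavelength, AU.
#' @param baseline_wander_length_nm Correlation length of the baseline
#'   wander; a squared-exponential covariance in wavelength, so a full-span
#'   grid carries roughly span/length independent wander directions.
#' @return A list of the variation parameters.
#' @export
measurement_variation <- function(offset_sd_au = 2e-3,
                                  slope_sd_au_per_nm = 2e-6,
                                  curvature_sd_au = 1e-3,
                                  pathlength_scale_sd = 0.003,
                                  temperature_jitter_c = 0.1,
                                  baseline_wander_sd_au = 3e-4,
                                  baseline_wander_length_nm = 150) {
  out <- list(offset_sd_au = offset_sd_au,
              slope_sd_au_per_nm = slope_sd_au_per_nm,
              curvature_sd_au = curvature_sd_au,
              pathlength_scale_sd = pathlength_scale_sd,
              temperature_jitter_c = temperature_jitter_c,
              baseline_wander_sd_au = baseline_wander_sd_au,
              baseline_wander_length_nm = baseline_wander_length_nm)
  for (k in names(out)) check_number(out[[k]], k, min = 0)
  out
}

# Cholesky-like square root of the squared-exponential wander covariance on
# the grid (eigendecomposition; tolerant of the near-singular tail).
wander_root <- function(grid, sd_au, length_nm) {
  if (sd_au == 0) return(NULL)
  k <- sd_au^2 * exp(-0.5 * outer(grid, grid, `-`)^2 / length_nm^2)
  e <- eigen(k, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
}

#' Simulate per-phantom mean calibration spectra for a whole design
#'
#' Draws each phantom's harmonized two-minute mean absorbance spectrum
#' directly: the noiseless forward spectrum, modified by the per-phantom
#' [measurement_variation()] effects (interface repositioning baseline,
#' pathlength scaling, temperature jitter), plus white noise of RMS
#' `sigma_scan / sqrt(n_scans)`, where `sigma_scan` and `n_scans` are the
#' profile's per-processed-scan noise and processed scan count. The noise
#' term is distribution-equivalent to simulating the full time series and
#' averaging, and keeps whole-design studies fast.
#'
#' @param design Design tibble from [build_design()].
#' @param profile An [instrument_profile()] or its name.
#' @param grid Target wavelength grid, nm.
#' @param lib An [absorptivity_library()].
#' @param variation A [measurement_variation()] model; set every SD to zero
#'   for idealized composition-only spectra.
#' @param seed Optional integer seed.
#' @return A calibration tibble: `phantom_id`, `glucose_mgdl`, `beads_mgdl`,
#'   `n_scans`, then one absorbance column (AU) per wavelength.
#' @export
simulate_calibration_dataset <- function(design, profile = "laser",
                                         grid = wavelength_grid(),
                                         lib = absorptivity_library(),
                                         variation = measurement_variation(),
                                         seed = NULL) {
  if (is.character(profile)) profile <- instrument_profile(profile)
  eff <- profile_effective(profile)
  sigma_mean <- eff$sigma_uau * 1e-6 / sqrt(eff$n_scans)
  mid <- mean(range(grid))
  half <- diff(range(grid)) / 2

  wr <- wander_root(grid, variation$baseline_wander_sd_au,
                    variation$baseline_wander_length_nm)

  with_seed_if(seed, {
    n <- nrow(design)
    temps <- lib$t_ref_c + rnorm(n, sd = variation$temperature_jitter_c)
    offs <- rnorm(n, sd = variation$offset_sd_au)
    slopes <- rnorm(n, sd = variation$slope_sd_au_per_nm)
    curvs <- rnorm(n, sd = variation$curvature_sd_au)
    scales <- 1 + rnorm(n, sd = variation$pathlength_scale_sd)
    mats <- purrr::map(seq_len(n), function(i) {
      a <- simulate_absorbance(design[i, ], grid, lib, temperature_c = temps[i])
      wander <- if (is.null(wr)) 0 else as.vector(wr %*% rnorm(ncol(wr)))
      scales[i] * a$absorbance_au + offs[i] + slopes[i] * (grid - mid) +
        curvs[i] * ((grid - mid) / half)^2 + wander +
        rnorm(length(grid), sd = sigma_mean)
    })
    m <- do.call(rbind, mats)
    colnames(m) <- as.character(grid)
    dplyr::bind_cols(
      tibble::tibble(phantom_id = design$phantom_id,
                     glucose_mgdl = design$glucose_mgdl,
                     beads_mgdl = design$beads_mgdl,
                     n_scans = eff$n_scans),
      tibble::as_tibble(m)
    )
  })
}
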