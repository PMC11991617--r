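# Harmonization of raw data into comparable absorbance datasets:
# demodulation, sampling-rate matching, duration matching, wavelength
# interpolation, absorbance transform and per-phantom averaging.

#' Demodulate a pulsed-laser modulation cycle into a single-beam spectrum
#'
#' For each laser, the intensity is the mean of its on-samples minus the mean
#' of the dark samples in the 100 us windows immediately before and after the
#' pulse. Output is ordered by increasing wavelength (or laser index when no
#' wavelength lookup is available).
#'
#' @param cycle A modulation-cycle tibble (`time_us`, `laser_index`, `value`),
#'   e.g. from [simulate_modulation_cycle()] or read from CSV.
#' @param wavelengths Optional wavelength (nm) per laser index; defaults to
#'   the `"wavelength_nm"` attribute of `cycle` if present.
#' @param window_us Dark window on each side of the pulse, microseconds.
#' @return A single-beam tibble with `wavelength_nm` (or `laser_index`) and
#'   `intensity`.
#' @export
demodulate <- function(cycle, wavelengths = attr(cycle, "wavelength_nm"),
                       window_us = 100) {
  lasers <- sort(unique(cycle$laser_index[cycle$laser_index > 0]))
  if (length(lasers) == 0) abort("Cycle contains no laser on-segments.")
  dark <- cycle[cycle$laser_index == -1L, ]

  intensity <- vapply(lasers, function(i) {
    on <- cycle[cycle$laser_index == i, ]
    t0 <- min(on$time_us)
    dt <- if (nrow(on) > 1) min(diff(sort(on$time_us))) else
      attr(cycle, "sample_interval_us") %||% abort("Cannot infer the sampling interval for single-sample pulses.")
    t1 <- max(on$time_us) + dt
    before <- dark$value[dark$time_us >= t0 - window_us & dark$time_us < t0]
    after <- dark$value[dark$time_us >= t1 & dark$time_us < t1 + window_us]
    need <- window_us / dt
    if (length(before) < need || length(after) < need) {
      abort(sprintf("Laser %d is missing a full %g us flanking dark segment.", i, window_us))
    }
    mean(on$value) - mean(c(before, after))
  }, double(1))

  if (!is.null(wavelengths)) {
    out <- tibble::tibble(wavelength_nm = wavelengths[lasers], intensity = intensity)
    dplyr::arrange(out, .data$wavelength_nm)
  } else {
    tibble::tibble(laser_index = lasers, intensity = intensity)
  }
}

#' Average consecutive scan pairs
#'
#' Non-overlapping consecutive pairs (1,2), (3,4), ... are averaged per
#' phantom, halving the sampling rate (15.15 -> 7.575 scans/s, reported as
#' 7.58). A trailing odd scan is dropped so all output scans carry equal
#' weight. The output timestamp is the mean of each pair's timestamps.
#'
#' @param spectra A wide spectra tibble with >= 2 scans per phantom.
#' @return A wide spectra tibble with half as many scans (per phantom).
#' @export
pairwise_average <- function(spectra) {
  one <- function(df) {
    n <- nrow(df)
    if (n < 2) abort("`pairwise_average()` needs at least 2 scans per phantom.")
    df <- df[order(df$timestamp_s), ]
    keep <- seq_len(n - n %% 2)
    g <- (keep + 1) %/% 2
    m <- rowsum(spectra_matrix(df[keep, ]), g) / 2
    ts <- as.vector(rowsum(df$timestamp_s[keep], g) / 2)
    new_spectra_tbl(m, wl_values(df), ts, phantom_id = df$phantom_id[1])
  }
  spectra |>
    dplyr::group_split(.data$phantom_id) |>
    purrr::map(one) |>
    dplyr::bind_rows()
}

#' Trim a time series to a time window
#'
#' Keeps scans with `keep_start_s <= timestamp_s < keep_end_s`. With the
#' defaults, a 7-minute series loses its first and last 2.5 minutes, leaving
#' the middle two minutes.
#'
#' @param spectra A wide spectra tibble.
#' @param keep_start_s,keep_end_s Window bounds in seconds.
#' @return The trimmed spectra tibble.
#' @export
trim_to_window <- function(spectra, keep_start_s = 150, keep_end_s = 270) {
  if (keep_end_s <= keep_start_s) abort("`keep_end_s` must be > `keep_start_s`.")
  out <- dplyr::filter(spectra, .data$timestamp_s >= keep_start_s,
                       .data$timestamp_s < keep_end_s)
  if (nrow(out) == 0) abort("Trim window contains no scans.")
  out
}

#' Resample spectra onto a target wavelength grid
#'
#' Shape-preserving piecewise-cubic (monotone Hermite, MATLAB `pchip`)
#' interpolation: interpolated values never overshoot the bracketing source
#' points and monotone stretches of the source stay monotone. No
#' extrapolation: the target grid must lie within the source span.
#'
#' @param x A long single spectrum (`wavelength_nm` + value column) or a wide
#'   spectra tibble (each scan resampled independently).
#' @param target Target wavelength grid, nm (strictly increasing).
#' @return `x` resampled onto `target`, same layout as the input.
#' @export
resample_to_grid <- function(x, target) {
  if (is.unsorted(target, strictly = TRUE)) abort("`target` must be strictly increasing.")
  if ("wavelength_nm" %in% names(x)) {
    src <- x$wavelength_nm
    check_span(src, target)
    val_col <- setdiff(names(x), "wavelength_nm")[1]
    out <- tibble::tibble(wavelength_nm = target,
                          value = pracma::pchip(src, x[[val_col]], target))
    names(out)[2] <- val_col
    return(out)
  }
  src <- wl_values(x)
  check_span(src, target)
  m <- spectra_matrix(x)
  res <- t(apply(m, 1, function(row) pracma::pchip(src, row, target)))
  new_spectra_tbl(res, target, x$timestamp_s, phantom_id = x$phantom_id)
}

check_span <- function(src, target) {
  if (min(target) < min(src) || max(target) > max(src)) {
    abort(sprintf("Target grid [%g, %g] nm extends beyond the source span [%g, %g] nm; extrapolation is not supported.",
                  min(target), max(target), min(src), max(src)))
  }
}

#' Transform single-beam intensities to absorbance
#'
#' A = -log10(I / I0). With `reference = "unit"` the transform is -log10(I);
#' any common reference cancels in 100% lines and is absorbed by PLS
#' centering.
#'
#' @param x A wide spectra tibble or a long single-beam spectrum.
#' @param reference "unit" (I0 = 1) or a numeric reference: scalar or one
#'   value per wavelength.
#' @return Same layout as `x` with values in AU (long output column
#'   `absorbance_au`).
#' @export
to_absorbance <- function(x, reference = "unit") {
  if ("wavelength_nm" %in% names(x)) {
    i0 <- if (identical(reference, "unit")) 1 else rep_len(reference, nrow(x))
    check_positive_intensity(x$intensity, x$wavelength_nm)
    return(tibble::tibble(wavelength_nm = x$wavelength_nm,
                          absorbance_au = -log10(x$intensity / i0)))
  }
  m <- spectra_matrix(x)
  wl <- wl_values(x)
  check_positive_intensity(m, wl)
  i0 <- if (identical(reference, "unit")) 1 else rep_len(reference, ncol(m))
  a <- -log10(sweep(m, 2, i0, `/`))
  out <- new_spectra_tbl(a, wl, x$timestamp_s, phantom_id = x$phantom_id)
  out
}

check_positive_intensity <- function(vals, wl) {
  if (any(vals <= 0)) {
    bad <- if (is.matrix(vals)) wl[apply(vals <= 0, 2, any)] else wl[vals <= 0]
    abort(paste0("Nonpositive intensities at wavelengths (nm): ",
                 paste(signif(unique(bad), 6), collapse = ", ")))
  }
}

#' Per-phantom mean absorbance spectrum
#'
#' Arithmetic mean over scans at each wavelength, per phantom; the number of
#' scans averaged is recorded in `n_scans`.
#'
#' @param spectra A wide absorbance spectra tibble (values in AU).
#' @return A tibble with `phantom_id`, `n_scans` and one column per
#'   wavelength.
#' @export
phantom_mean_spectrum <- function(spectra) {
  spectra |>
    dplyr::summarise(
      n_scans = dplyr::n(),
      dplyr::across(dplyr::all_of(wl_cols(spectra)), mean),
      .by = "phantom_id"
    )
}
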