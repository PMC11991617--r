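# 100% line computation, quadratic detrending, RMS noise / SNR statistics,
# duration scaling and the noise-injection calibration.

#' Compute a 100% line from two back-to-back single-beam spectra
#'
#' y(lambda) = -log10(s1 / s2). Ideally flat at zero absorbance; offset,
#' slope and curvature reflect scattering and temperature differences between
#' the two scans, and the residual scatter is instrument noise.
#'
#' @param s1,s2 Single-beam tibbles (`wavelength_nm`, `intensity`) on the
#'   same grid, with positive intensities.
#' @return A tibble with `wavelength_nm` and `value_au`.
#' @export
hundred_percent_line <- function(s1, s2) {
  if (!isTRUE(all.equal(s1$wavelength_nm, s2$wavelength_nm))) {
    abort("The two spectra must share the same wavelength grid.")
  }
  check_positive_intensity(s1$intensity, s1$wavelength_nm)
  check_positive_intensity(s2$intensity, s2$wavelength_nm)
  tibble::tibble(wavelength_nm = s1$wavelength_nm,
                 value_au = -log10(s1$intensity / s2$intensity))
}

# Orthonormal polynomial basis (including the constant) on centered/scaled x.
poly_basis <- function(x, k) {
  xs <- if (diff(range(x)) > 0) 2 * (x - mean(range(x))) / diff(range(x)) else x * 0
  qr.Q(qr(outer(xs, 0:k, `^`)))
}

#' Detrend a 100% line with a low-order polynomial
#'
#' Least-squares polynomial of order `k` (default 2: offset, slope,
#' curvature) in wavelength, fitted on a centered and scaled regressor for
#' conditioning; residuals carry the noise. `regressor = "index"` fits
#' against the point index instead (the two differ only for non-uniform
#' grids).
#'
#' @param line A tibble with `wavelength_nm` and `value_au`.
#' @param k Polynomial order (>= 0).
#' @param regressor "wavelength" or "index".
#' @return The line tibble with added `fitted_au` and `residual_au` columns
#'   and attribute `k`.
#' @export
detrend <- function(line, k = 2, regressor = c("wavelength", "index")) {
  regressor <- match.arg(regressor)
  if (k < 0) abort("`k` must be >= 0.")
  x <- if (regressor == "wavelength") line$wavelength_nm else seq_len(nrow(line))
  if (nrow(line) <= k + 1) abort("Need more points than polynomial coefficients.")
  q <- poly_basis(x, k)
  fitted <- as.vector(q %*% crossprod(q, line$value_au))
  out <- dplyr::mutate(line, fitted_au = fitted,
                       residual_au = .data$value_au - fitted)
  attr(out, "k") <- k
  out
}

#' RMS noise of a detrended 100% line
#'
#' RMS = sqrt( sum(y_i^2) / (N - 1 - k) ), with y the detrended residuals, N
#' the number of wavelengths and k the detrending polynomial order. The
#' denominator is N - 1 - k verbatim; with k = 2 this equals the quadratic
#' fit's residual degrees of freedom N - 3, so the estimator is approximately
#' unbiased for white noise. Reported in micro-absorbance units (uAU).
#'
#' @param line A detrended line from [detrend()], or a numeric vector of
#'   residuals in AU.
#' @param k Polynomial order used for detrending (taken from the line's
#'   attribute when available).
#' @return RMS noise, uAU.
#' @export
rms_noise <- function(line, k = attr(line, "k") %||% 2) {
  y <- if (is.numeric(line)) line else line$residual_au
  n <- length(y)
  if (n - 1 - k < 1) abort(sprintf("Need N > k + 1 points (N = %d, k = %d).", n, k))
  sqrt(sum(y^2) / (n - 1 - k)) * 1e6
}

#' Signal-to-noise ratio from an RMS noise level
#'
#' SNR = (2.303 * RMS)^-1 with RMS in AU; the 2.303 converts the base-10
#' absorbance noise to the natural-log (relative intensity) scale.
#'
#' @param rms_uau RMS noise in uAU (zero noise gives an infinite SNR).
#' @return Dimensionless SNR. 15.0 uAU gives 28,944 (28,900 at 3 significant
#'   figures); 33.8 uAU gives 12,847 (12,800).
#' @export
snr <- function(rms_uau) {
  check_number(rms_uau, "rms_uau", min = 0)
  ifelse(rms_uau == 0, Inf, 1 / (2.303 * rms_uau * 1e-6))
}

#' Scale an RMS noise level to a longer averaging duration
#'
#' Assuming white noise, averaging N spectra reduces the RMS by 1/sqrt(N).
#' Fractional scan counts (e.g. 8.33 scans/s x 60 s = 499.8) are used as-is.
#'
#' @param rms_uau Single-scan RMS noise, uAU.
#' @param n_scans_averaged Number of averaged spectra (> 0, may be
#'   fractional).
#' @return Scaled RMS noise, uAU.
#' @export
scale_rms_to_duration <- function(rms_uau, n_scans_averaged) {
  check_number(n_scans_averaged, "n_scans_averaged", min = 0, strict_min = TRUE)
  rms_uau / sqrt(n_scans_averaged)
}

#' Per-line RMS noise for a spectral dataset
#'
#' For each phantom, 100% lines are formed from consecutive non-overlapping
#' scan pairs (1,2), (3,4), ... — so lines are independent under white noise —
#' then detrended with an order-`k` polynomial and summarized with the
#' RMS statistic.
#'
#' @param spectra A wide single-beam spectra tibble (one or more phantoms,
#'   >= 2 scans each).
#' @param k Detrending polynomial order.
#' @param regressor Passed to [detrend()].
#' @return A tibble with one row per 100% line: `phantom_id`, `line`,
#'   `scan_a`, `scan_b`, `rms_uau`.
#' @export
benchmark_spectra <- function(spectra, k = 2, regressor = c("wavelength", "index")) {
  regressor <- match.arg(regressor)
  wl <- wl_values(spectra)
  if (length(wl) - 1 - k < 1) abort("Too few wavelengths for the requested detrend order.")
  x <- if (regressor == "wavelength") wl else seq_along(wl)
  q <- poly_basis(x, k)

  one <- function(df) {
    df <- df[order(df$timestamp_s), ]
    n <- nrow(df)
    if (n < 2) abort("Each phantom needs at least 2 scans.")
    m <- spectra_matrix(df)
    a <- seq(1, n - 1, by = 2)
    lines <- -log10(m[a, , drop = FALSE] / m[a + 1, , drop = FALSE])
    resid <- lines - lines %*% q %*% t(q)
    tibble::tibble(
      phantom_id = df$phantom_id[1],
      line = seq_along(a), scan_a = a, scan_b = a + 1,
      rms_uau = sqrt(rowSums(resid^2) / (length(wl) - 1 - k)) * 1e6
    )
  }
  spectra |>
    dplyr::group_split(.data$phantom_id) |>
    purrr::map(one) |>
    dplyr::bind_rows()
}

#' Summarize a per-line RMS table
#'
#' @param per_line Output of [benchmark_spectra()].
#' @param by_phantom Summarize per phantom instead of overall.
#' @param n_scans_one_minute Optional scan count for a one-minute theoretical
#'   scaling of the median (1/sqrt(N) law); e.g. 8.33 x 60 = 499.8.
#' @return A tibble with `n_lines`, `median_uau`, `q1_uau`, `q3_uau`,
#'   `snr_median`, and `median_one_minute_uau` when requested.
#' @export
rms_summary <- function(per_line, by_phantom = FALSE,
                        n_scans_one_minute = NULL) {
  grp <- if (by_phantom) "phantom_id" else character()
  out <- per_line |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      median_uau = median(.data$rms_uau),
      q1_uau = quantile(.data$rms_uau, 0.25, names = FALSE),
      q3_uau = quantile(.data$rms_uau, 0.75, names = FALSE),
      .by = dplyr::all_of(grp)
    ) |>
    dplyr::mutate(snr_median = snr(.data$median_uau))
  if (!is.null(n_scans_one_minute)) {
    out <- dplyr::mutate(out, median_one_minute_uau =
                           scale_rms_to_duration(.data$median_uau, n_scans_one_minute))
  }
  out
}

#' Add white absorbance noise to a spectral dataset
#'
#' Noise of the given RMS (uAU) is added in the absorbance domain:
#' I' = I * 10^(-e), e ~ N(0, sigma).
#'
#' @param spectra A wide single-beam spectra tibble.
#' @param sigma_uau Noise RMS per scan per wavelength, uAU.
#' @param seed Optional seed.
#' @return The noisy spectra tibble.
#' @export
add_spectral_noise <- function(spectra, sigma_uau, seed = NULL) {
  check_number(sigma_uau, "sigma_uau", min = 0)
  m <- spectra_matrix(spectra)
  e <- with_seed_if(seed, matrix(rnorm(length(m), sd = sigma_uau * 1e-6), nrow = nrow(m)))
  out <- spectra
  out[wl_cols(spectra)] <- tibble::as_tibble(m * 10^(-e))
  out
}

#' Calibrate the injection noise needed to reach a target median RMS
#'
#' Bisection on the added Gaussian absorbance noise sigma until the dataset's
#' median 100% line RMS is within `tol_uau` of the target. One fixed
#' standard-normal draw (under `seed`) is scaled by sigma at every
#' evaluation, which makes the achieved median exactly monotone in sigma.
#'
#' @param spectra A wide single-beam spectra tibble.
#' @param target_median_rms_uau Target median RMS, uAU; must be at or above
#'   the dataset's baseline median.
#' @param tol_uau Convergence tolerance on the achieved median, uAU.
#' @param k Detrend order for the RMS computation.
#' @param seed Seed for the fixed noise draw.
#' @param max_iter Bisection iteration cap.
#' @return A list with `sigma_uau` (the per-scan noise to add),
#'   `achieved_median_uau`, `base_median_uau`, and `noisy` (the spectra with
#'   that noise applied).
#' @export
calibrate_injection_noise <- function(spectra, target_median_rms_uau,
                                      tol_uau = 1, k = 2, seed = 1,
                                      max_iter = 60) {
  m <- spectra_matrix(spectra)
  z <- with_seed_if(seed, matrix(rnorm(length(m)), nrow = nrow(m)))
  apply_sigma <- function(sigma_uau) {
    out <- spectra
    out[wl_cols(spectra)] <- tibble::as_tibble(m * 10^(-(sigma_uau * 1e-6) * z))
    out
  }
  med <- function(sigma_uau) {
    median(benchmark_spectra(apply_sigma(sigma_uau), k = k)$rms_uau)
  }

  base <- med(0)
  if (target_median_rms_uau < base - tol_uau) {
    abort(sprintf("Target median (%.1f uAU) is below the dataset baseline (%.1f uAU); noise cannot be removed.",
                  target_median_rms_uau, base))
  }
  lo <- 0
  hi <- max(target_median_rms_uau, 1)
  while (med(hi) < target_median_rms_uau) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- med(mid)
    if (abs(val - target_median_rms_uau) <= tol_uau) {
      lo <- hi <- mid
      break
    }
    if (val < target_median_rms_uau) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  list(sigma_uau = sigma, achieved_median_uau = med(sigma),
       base_median_uau = base, noisy = apply_sigma(sigma))
}
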