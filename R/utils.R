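# Shared helpers for the wide spectra tibble layout.
#
# A "spectra tibble" has one row per scan: optional metadata columns
# (phantom_id, timestamp_s, scan, n_scans) followed by one numeric column per
# wavelength, named with the wavelength in nm (e.g. "1350", "1359.909...").
# Long single spectra are tibbles with a wavelength_nm column plus a value
# column (intensity or absorbance_au).

spectra_meta_cols <- c("phantom_id", "timestamp_s", "scan", "n_scans", "glucose_mgdl", "beads_mgdl")

is_wl_name <- function(nm) !is.na(suppressWarnings(as.numeric(nm)))

#' Wavelength columns of a wide spectra tibble
#'
#' Columns whose names parse as numbers are treated as wavelengths (nm);
#' everything else is metadata.
#'
#' @param x A wide spectra tibble.
#' @return `wl_cols()`: character vector of column names. `wl_values()`:
#'   numeric wavelengths in nm. `spectra_matrix()`: the scans-by-wavelengths
#'   numeric matrix.
#' @export
wl_cols <- function(x) {
  names(x)[is_wl_name(names(x))]
}

#' @rdname wl_cols
#' @export
wl_values <- function(x) as.numeric(wl_cols(x))

#' @rdname wl_cols
#' @export
spectra_matrix <- function(x) {
  m <- as.matrix(x[wl_cols(x)])
  storage.mode(m) <- "double"
  m
}

# Assemble a wide spectra tibble from a scans x wavelengths matrix.
new_spectra_tbl <- function(values, wavelengths, timestamp_s, phantom_id = NA_character_) {
  values <- matrix(values, ncol = length(wavelengths))
  stopifnot(length(timestamp_s) == nrow(values))
  colnames(values) <- as.character(wavelengths)
  dplyr::bind_cols(
    tibble::tibble(phantom_id = phantom_id, timestamp_s = as.double(timestamp_s)),
    tibble::as_tibble(values)
  )
}

#' Pivot spectra between wide and long layouts
#'
#' @param x A wide spectra tibble (for `spectra_longer()`) or a long tibble
#'   with `wavelength_nm` and a value column (for `spectra_wider()`).
#' @param values_to,values_from Name of the value column in the long layout.
#' @return A tibble in the other layout.
#' @export
spectra_longer <- function(x, values_to = "intensity") {
  tidyr::pivot_longer(x, cols = dplyr::all_of(wl_cols(x)),
                      names_to = "wavelength_nm", values_to = values_to,
                      names_transform = list(wavelength_nm = as.numeric))
}

#' @rdname spectra_longer
#' @export
spectra_wider <- function(x, values_from = "intensity") {
  tidyr::pivot_wider(x, names_from = "wavelength_nm", values_from = dplyr::all_of(values_from))
}

#' Scan rate of a spectra time series
#'
#' Inferred from the median spacing of the timestamps; `reported_scan_rate()`
#' rounds half-up at 2 decimals (15.15/2 = 7.575 reports as 7.58).
#'
#' @param x A wide spectra tibble with a `timestamp_s` column and >= 2 scans.
#' @return Scans per second.
#' @export
scan_rate <- function(x) {
  ts <- sort(unique(x$timestamp_s[x$phantom_id == x$phantom_id[1]]))
  if (length(ts) < 2) abort("Need at least two scans to infer a scan rate.")
  1 / median(diff(ts))
}

#' @rdname scan_rate
#' @export
reported_scan_rate <- function(x) {
  r <- if (is.numeric(x)) x else scan_rate(x)
  round_half_up(r, 2)
}

# Round half away from zero at `digits` decimals, with a 1e-9 guard so values
# stored in binary just below a decimal boundary (e.g. 7.575) round up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite number.", name))
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    op <- if (strict_min) ">" else ">="
    abort(sprintf("`%s` must be %s %g.", name, op, min))
  }
  invisible(x)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Evaluate a sum of Gaussian bands described by a tibble with columns
# center_nm, sd_nm, amplitude at wavelengths `wl`.
eval_bands <- function(bands, wl) {
  if (is.null(bands) || nrow(bands) == 0) return(rep(0, length(wl)))
  out <- rep(0, length(wl))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] * exp(-0.5 * ((wl - bands$center_nm[i]) / bands$sd_nm[i])^2)
  }
  out
}
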