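# ggplot2 figures for each result type.

#' Plot 100% lines
#'
#' @param lines A tibble of one or more lines with `wavelength_nm`,
#'   `value_au` (and optionally `residual_au` after [detrend()]); a `line`
#'   column distinguishes multiple lines.
#' @param residuals Plot detrended residuals instead of the raw lines.
#' @return A ggplot.
#' @export
plot_hundred_percent_lines <- function(lines, residuals = FALSE) {
  ycol <- if (residuals) "residual_au" else "value_au"
  p <- ggplot2::ggplot(lines, ggplot2::aes(x = .data$wavelength_nm,
                                           y = .data[[ycol]] * 1e6))
  if ("line" %in% names(lines)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$line), alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = if (residuals) "Detrended 100% line (µAU)" else "100% line (µAU)")
}

#' Boxplot of per-line RMS noise values
#'
#' @param per_line Output of [benchmark_spectra()]; bind rows from several
#'   profiles with a `profile` column to compare instruments.
#' @param by Grouping column ("profile" if present, else "phantom_id").
#' @return A ggplot.
#' @export
plot_rms_boxplot <- function(per_line, by = if ("profile" %in% names(per_line)) "profile" else "phantom_id") {
  ggplot2::ggplot(per_line, ggplot2::aes(x = .data[[by]], y = .data$rms_uau)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "100% line RMS noise (µAU)")
}

#' Concentration correlation plot for cross-validated predictions
#'
#' Predicted versus reference glucose concentrations with the unity line.
#'
#' @param object A `lopo_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lopo_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$glucose_mgdl, y = .data$predicted_mgdl)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Reference glucose (mg/dL)",
                  y = "Predicted glucose (mg/dL)",
                  subtitle = sprintf("SECV = %.2f mg/dL, %d factors",
                                     object$secv_mgdl, object$n_factors))
}

#' SECV surface of a wavelength-window grid search
#'
#' Tile plot of the best (over factor counts) SECV for each window.
#'
#' @param object A `pls_grid_search` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pls_grid_search <- function(object, ...) {
  best <- object$surface |>
    dplyr::slice_min(.data$secv_mgdl, n = 1, with_ties = FALSE,
                     by = c("start_nm", "end_nm"))
  ggplot2::ggplot(best, ggplot2::aes(x = .data$start_nm, y = .data$width_nm,
                                     fill = .data$secv_mgdl)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "SECV (mg/dL)") +
    ggplot2::labs(x = "Window start (nm)", y = "Window width (nm)")
}

#' SECV as a function of the number of PLS factors
#'
#' @param curve A tibble from [secv_curve()]; bind rows from several runs
#'   with a `label` column to overlay (e.g. correct vs randomized labels).
#' @return A ggplot.
#' @export
plot_secv_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_factors,
                                           y = .data$secv_mgdl))
  if ("label" %in% names(curve)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$label)) +
      ggplot2::geom_point(ggplot2::aes(color = .data$label))
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "Number of PLS factors", y = "SECV (mg/dL)")
}
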