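# Leave-one-phantom-out cross-validation, SECV, wavelength-window grid
# search, regression diagnostics and the randomized-label control.

#' Standard error of cross-validation
#'
#' SECV = sqrt( sum((y - yhat)^2) / N ), with denominator N (not N - 1).
#'
#' @param actual,predicted Reference and cross-validated predicted
#'   concentrations, mg/dL.
#' @return SECV in mg/dL.
#' @export
secv <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have the same length.")
  }
  sqrt(mean((actual - predicted)^2))
}

# Leave-one-phantom-out predictions for factor counts 1..a_max: one SIMPLS
# fit per fold, cumulative regression vectors give every factor count. Folds
# hitting rank deficiency truncate; the returned matrix covers factor counts
# attainable in every fold.
lopo_prediction_matrix <- function(x, y, a_max) {
  n <- nrow(x)
  pred <- matrix(NA_real_, n, a_max)
  attained <- a_max
  for (i in seq_len(n)) {
    fit <- simpls_fit(x[-i, , drop = FALSE], y[-i], a_max, truncate = TRUE)
    attained <- min(attained, fit$attained)
    xc <- x[i, ] - fit$x_mean
    pred[i, seq_len(fit$attained)] <- as.vector(xc %*% fit$coefs) + fit$y_mean
  }
  pred[, seq_len(attained), drop = FALSE]
}

#' Leave-one-phantom-out cross-validation of a PLS model
#'
#' For each phantom, a SIMPLS model is fitted on the remaining N - 1 spectra
#' and used to predict the left-out phantom's glucose concentration; SECV
#' summarizes the N held-out predictions.
#'
#' @param data A calibration tibble (see [fit_pls()]).
#' @param n_factors Number of latent variables.
#' @param window Optional wavelength window `c(min_nm, max_nm)`.
#' @return A `lopo_cv` object: `predictions` tibble (`phantom_id`,
#'   `glucose_mgdl`, `predicted_mgdl`), `secv_mgdl`, `n_factors`, `window`.
#' @export
lopo_cv <- function(data, n_factors, window = NULL) {
  ds <- pls_design(data, window)
  a_max <- min(n_factors, nrow(ds$x) - 2, ncol(ds$x))
  if (a_max < n_factors) {
    abort(sprintf("`n_factors` = %d exceeds the attainable maximum %d for this fold size.",
                  n_factors, a_max))
  }
  pred_mat <- lopo_prediction_matrix(ds$x, ds$y, n_factors)
  if (ncol(pred_mat) < n_factors) {
    abort(sprintf("`n_factors` = %d exceeds the attainable rank %d of the fold spectra.",
                  n_factors, ncol(pred_mat)))
  }
  pred <- pred_mat[, n_factors]
  structure(
    list(
      predictions = tibble::tibble(phantom_id = data$phantom_id,
                                   glucose_mgdl = ds$y,
                                   predicted_mgdl = pred),
      secv_mgdl = secv(ds$y, pred),
      n_factors = n_factors,
      window = window %||% range(ds$wl)
    ),
    class = "lopo_cv"
  )
}

#' SECV as a function of the number of PLS factors
#'
#' One leave-one-phantom-out pass produces the full SECV-vs-factor curve
#' (the basis of the factor-selection plots).
#'
#' @param data A calibration tibble.
#' @param factors Integer vector of factor counts to evaluate.
#' @param window Optional wavelength window.
#' @return A tibble with `n_factors` and `secv_mgdl`.
#' @export
secv_curve <- function(data, factors = 1:20, window = NULL) {
  ds <- pls_design(data, window)
  a_max <- min(max(factors), nrow(ds$x) - 2, ncol(ds$x))
  pred <- lopo_prediction_matrix(ds$x, ds$y, a_max)
  keep <- factors[factors <= ncol(pred)]
  tibble::tibble(
    n_factors = keep,
    secv_mgdl = vapply(keep, function(a) secv(ds$y, pred[, a]), double(1))
  )
}

#' Grid search over wavelength windows and factor counts
#'
#' Enumerates contiguous wavelength windows on a lattice anchored at the grid
#' minimum (window widths from `min_width_nm` growing in `width_step_nm`
#' increments up to the full span; start positions every `start_step_nm`),
#' evaluates the leave-one-phantom-out SECV for each factor count, and
#' returns the full SECV surface with its optimum. Ties are broken by fewer
#' factors, then narrower window, then lower window start. Windows containing
#' fewer than 2 wavelengths are skipped and recorded.
#'
#' @param data A calibration tibble.
#' @param min_width_nm,width_step_nm,start_step_nm Window lattice parameters,
#'   nm.
#' @param factors Factor counts to evaluate.
#' @return A `pls_grid_search` object: `surface` tibble (`start_nm`,
#'   `end_nm`, `width_nm`, `n_factors`, `secv_mgdl`), `optimum` (one-row
#'   tibble), `skipped` (tibble of skipped windows).
#' @export
grid_search <- function(data, min_width_nm = 50, width_step_nm = 50,
                        start_step_nm = 50, factors = 1:20) {
  wl <- wl_values(data)
  span <- max(wl) - min(wl)
  if (span < min_width_nm) abort("Grid span is smaller than the minimum window width.")
  widths <- seq(min_width_nm, span, by = width_step_nm)
  if (max(widths) < span) widths <- c(widths, span)
  starts <- seq(min(wl), max(wl) - min_width_nm, by = start_step_nm)

  surface <- list()
  skipped <- list()
  seen <- character()
  for (w in widths) {
    for (s in starts) {
      e <- min(s + w, max(wl))
      keep <- wl >= s & wl <= e
      key <- paste(range(which(keep)), collapse = "-")
      if (sum(keep) < 2) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(start_nm = s, end_nm = e)
        next
      }
      if (key %in% seen) next
      seen <- c(seen, key)
      curve <- secv_curve(data, factors = factors, window = c(s, e))
      surface[[length(surface) + 1]] <- dplyr::mutate(
        curve, start_nm = s, end_nm = e, width_nm = e - s, .before = 1)
    }
  }
  surface <- dplyr::bind_rows(surface)
  opt <- surface |>
    dplyr::arrange(.data$secv_mgdl, .data$n_factors, .data$width_nm, .data$start_nm) |>
    dplyr::slice(1)
  structure(
    list(surface = surface, optimum = opt,
         skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
           tibble::tibble(start_nm = double(), end_nm = double())),
    class = "pls_grid_search"
  )
}

#' @export
print.pls_grid_search <- function(x, ...) {
  o <- x$optimum
  cat(sprintf("PLS grid search: %d (window, factor) combinations\n", nrow(x$surface)))
  cat(sprintf("Optimum: %.0f-%.0f nm, %d factors, SECV = %.2f mg/dL\n",
              o$start_nm, o$end_nm, o$n_factors, o$secv_mgdl))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `pls_grid_search`.
#' @param ... Unused.
#' @export
tidy.pls_grid_search <- function(x, ...) x$surface

#' @rdname grid_search
#' @export
glance.pls_grid_search <- function(x, ...) x$optimum

#' Regression diagnostics of cross-validated predictions
#'
#' Ordinary least squares of the predicted on the reference concentrations:
#' slope and intercept with standard errors, plus the coefficient of
#' determination. Perfect predictions give slope 1, intercept 0, R^2 = 1.
#'
#' @param cv A `lopo_cv` object (or a tibble with `glucose_mgdl` and
#'   `predicted_mgdl`).
#' @return A one-row tibble: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r_squared`, `secv_mgdl` (when available).
#' @export
regression_diagnostics <- function(cv) {
  preds <- if (inherits(cv, "lopo_cv")) cv$predictions else cv
  fit <- lm(predicted_mgdl ~ glucose_mgdl, data = preds)
  sm <- summary(fit)
  tibble::tibble(
    slope = coef(fit)[["glucose_mgdl"]],
    slope_se = sm$coefficients["glucose_mgdl", "Std. Error"],
    intercept = coef(fit)[["(Intercept)"]],
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared,
    secv_mgdl = if (inherits(cv, "lopo_cv")) cv$secv_mgdl else NA_real_
  )
}

#' @export
print.lopo_cv <- function(x, ...) {
  cat(sprintf("Leave-one-phantom-out CV: %d phantoms, %d factors, %.0f-%.0f nm\n",
              nrow(x$predictions), x$n_factors, x$window[1], x$window[2]))
  cat(sprintf("SECV = %.2f mg/dL\n", x$secv_mgdl))
  invisible(x)
}

#' Tidy cross-validation predictions
#'
#' @param x A `lopo_cv` object.
#' @param ... Unused.
#' @return The per-phantom prediction tibble.
#' @export
tidy.lopo_cv <- function(x, ...) x$predictions

#' One-row cross-validation summary
#'
#' @param x A `lopo_cv` object.
#' @param ... Unused.
#' @return A tibble with SECV, factor count, window and the regression
#'   diagnostics.
#' @export
glance.lopo_cv <- function(x, ...) {
  diag <- regression_diagnostics(x)
  dplyr::bind_cols(
    tibble::tibble(secv_mgdl = x$secv_mgdl, n_factors = x$n_factors,
                   window_min_nm = x$window[1], window_max_nm = x$window[2]),
    dplyr::select(diag, -"secv_mgdl")
  )
}

#' Randomize glucose label assignments
#'
#' Permutes the glucose concentrations uniformly at random across phantoms
#' (the label multiset is preserved), breaking any true spectrum-label
#' association. A model trained on randomized labels can at best predict the
#' mean label, so its SECV approaches the label standard deviation.
#'
#' @param data A calibration tibble.
#' @param seed Optional seed for a reproducible permutation.
#' @return The tibble with `glucose_mgdl` permuted.
#' @export
randomize_labels <- function(data, seed = NULL) {
  perm <- with_seed_if(seed, sample.int(nrow(data)))
  dplyr::mutate(data, glucose_mgdl = .data$glucose_mgdl[perm])
}
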