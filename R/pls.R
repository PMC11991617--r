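# In-house SIMPLS partial least squares regression.
#
# de Jong's SIMPLS for a univariate response: deterministic (no iteration
# tolerance), operating on column-centered spectra and a centered label.
# Cumulative regression vectors B_a = R[, 1:a] %*% Q[1:a] are stored for every
# factor count a, so predictions at any number of factors come from one fit.

simpls_fit <- function(x, y, n_factors, truncate = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  a_max <- min(n - 1, p)
  if (n_factors < 1 || n_factors > a_max) {
    abort(sprintf("`n_factors` must be in 1..%d for %d rows and %d wavelengths.",
                  a_max, n, p))
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  x0 <- sweep(x, 2, x_mean)
  y0 <- y - y_mean

  s <- crossprod(x0, y0)
  r_mat <- matrix(0, p, n_factors)
  q_vec <- numeric(n_factors)
  v_mat <- matrix(0, p, n_factors)
  t_mat <- matrix(0, n, n_factors)
  nt1 <- NULL
  attained <- n_factors
  for (a in seq_len(n_factors)) {
    r <- s
    t_sc <- x0 %*% r
    nt <- sqrt(sum(t_sc^2))
    if (is.null(nt1)) nt1 <- nt
    # rank check relative to the first component's scale
    if (nt <= nt1 * 1e-10) {
      if (!truncate) {
        abort(sprintf("Rank deficiency: only %d factors are attainable (requested %d).",
                      a - 1, n_factors))
      }
      attained <- a - 1
      if (attained == 0) abort("Spectra have no variance; cannot fit any factor.")
      r_mat <- r_mat[, seq_len(attained), drop = FALSE]
      q_vec <- q_vec[seq_len(attained)]
      t_mat <- t_mat[, seq_len(attained), drop = FALSE]
      break
    }
    t_sc <- t_sc / nt
    r <- r / nt
    p_load <- crossprod(x0, t_sc)
    q_vec[a] <- sum(y0 * t_sc)
    v <- p_load
    if (a > 1) {
      vv <- v_mat[, seq_len(a - 1), drop = FALSE]
      v <- v - vv %*% crossprod(vv, p_load)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    r_mat[, a] <- r
    v_mat[, a] <- v
    t_mat[, a] <- t_sc
  }
  coefs <- sapply(seq_len(attained), function(a) {
    r_mat[, seq_len(a), drop = FALSE] %*% q_vec[seq_len(a)]
  })
  list(x_mean = x_mean, y_mean = y_mean, coefs = matrix(coefs, nrow = p),
       weights = r_mat, scores = t_mat, loadings_q = q_vec,
       attained = attained)
}

# Extract the spectra matrix, labels and wavelengths of a calibration tibble,
# optionally restricted to a wavelength window [min, max] nm.
pls_design <- function(data, window = NULL) {
  wl <- wl_values(data)
  keep <- rep(TRUE, length(wl))
  if (!is.null(window)) {
    keep <- wl >= window[1] & wl <= window[2]
    if (sum(keep) < 2) {
      abort(sprintf("Window [%g, %g] nm contains fewer than 2 wavelengths.",
                    window[1], window[2]))
    }
  }
  cols <- wl_cols(data)[keep]
  x <- as.matrix(data[cols])
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(data$glucose_mgdl)) abort("Calibration data contain missing values.")
  list(x = x, y = data$glucose_mgdl, wl = wl[keep], cols = cols)
}

#' Fit a SIMPLS calibration model
#'
#' Partial least squares regression of glucose concentration on
#' column-centered absorbance spectra (no variance scaling), using the
#' deterministic SIMPLS algorithm. Prediction is affine in the input
#' spectrum; the training-mean spectrum predicts the training-mean label.
#'
#' @param data A calibration tibble: `phantom_id`, `glucose_mgdl` and one
#'   absorbance column per wavelength (e.g. from
#'   [simulate_calibration_dataset()]).
#' @param n_factors Number of latent variables, between 1 and
#'   `min(rows - 1, wavelengths)`.
#' @param window Optional wavelength window `c(min_nm, max_nm)` restricting
#'   the spectra.
#' @return A `pls_model` object with methods [predict()], [tidy()] and
#'   [glance()].
#' @export
fit_pls <- function(data, n_factors, window = NULL) {
  ds <- pls_design(data, window)
  fit <- simpls_fit(ds$x, ds$y, n_factors)
  structure(
    c(fit, list(n_factors = n_factors, wavelength_nm = ds$wl, cols = ds$cols,
                window = window %||% range(ds$wl), n_train = nrow(ds$x))),
    class = "pls_model"
  )
}

#' Predict glucose concentrations from a fitted PLS model
#'
#' @param object A `pls_model` from [fit_pls()].
#' @param newdata A calibration-style tibble (wavelength columns matched by
#'   name) or a numeric matrix/vector already aligned to the model's
#'   wavelengths.
#' @param n_factors Number of factors to use (defaults to the fitted count;
#'   0 gives the degenerate mean-label predictor used for diagnostics).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, mg/dL.
#' @export
predict.pls_model <- function(object, newdata, n_factors = object$n_factors, ...) {
  x <- if (is.data.frame(newdata)) {
    missing <- setdiff(object$cols, names(newdata))
    if (length(missing)) abort("`newdata` is missing model wavelength columns.")
    as.matrix(newdata[object$cols])
  } else {
    matrix(newdata, ncol = length(object$x_mean))
  }
  storage.mode(x) <- "double"
  if (n_factors == 0) return(rep(object$y_mean, nrow(x)))
  if (n_factors < 0 || n_factors > ncol(object$coefs)) {
    abort(sprintf("`n_factors` must be in 0..%d.", ncol(object$coefs)))
  }
  b <- object$coefs[, n_factors]
  as.vector(sweep(x, 2, object$x_mean) %*% b + object$y_mean)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("SIMPLS model: %d factors, %d training spectra, %d wavelengths (%.0f-%.0f nm)\n",
              x$n_factors, x$n_train, length(x$wavelength_nm),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Tidy a fitted PLS model into per-wavelength coefficients
#'
#' @param x A `pls_model`.
#' @param n_factors Factor count for the reported regression vector.
#' @param ... Unused.
#' @return A tibble with `wavelength_nm` and `coefficient`
#'   (mg/dL per AU).
#' @export
tidy.pls_model <- function(x, n_factors = x$n_factors, ...) {
  tibble::tibble(wavelength_nm = x$wavelength_nm,
                 coefficient = x$coefs[, n_factors])
}

#' One-row summary of a fitted PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with `n_factors`, `n_train`, `n_wavelengths`,
#'   `window_min_nm`, `window_max_nm`.
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors, n_train = x$n_train,
                 n_wavelengths = length(x$wavelength_nm),
                 window_min_nm = x$window[1], window_max_nm = x$window[2])
}
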