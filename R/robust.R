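#' Huber M-estimation by iteratively reweighted least squares
#'
#' Core robust linear-regression solver. Residuals are rescaled each
#' iteration by a median-absolute-deviation scale estimate; observations with
#' standardised residuals within the tuning constant `k` get weight 1, larger
#' residuals get weight `k / |r / s|`. With no outliers and a very large `k`
#' the fit reduces to ordinary least squares.
#'
#' @param x Model matrix (including the intercept column).
#' @param y Response vector.
#' @param k Huber tuning constant (default 1.345, 95% efficiency under
#'   Gaussian errors).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol Convergence tolerance on the coefficient change (default 1e-8).
#' @return A list with `coefficients`, `weights` (final IRLS weights),
#'   `residuals`, `scale`, `iterations`, `converged`.
#' @keywords internal
huber_irls <- function(x, y, k = 1.345, max_iter = 50, tol = 1e-8) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    abort("`x` and `y` sizes differ.", class = "effortsens_domain_error")
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "effortsens_rank_error")
  }
  beta <- qr.coef(qrx, y)
  w <- rep(1, length(y))
  converged <- FALSE
  iter <- 0
  s <- 1
  for (iter in seq_len(max_iter)) {
    r <- y - drop(x %*% beta)
    s <- mad(r, center = 0)
    if (s < .Machine$double.eps^0.5) {
      # (near-)exact fit: weights are all 1 and the solution is the LS fit
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)
    fit <- stats::lm.wfit(x, y, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(coefficients = beta, weights = w, residuals = y - drop(x %*% beta),
       scale = s, iterations = iter, converged = converged)
}

#' Estimate one participant's force and failure sensitivity
#'
#' Fits `rating ~ force_predictor + failure + hand` by Huber robust
#' regression on one participant's feature rows. The force predictor is the
#' squared force fraction by default (the quadratic link selected for this
#' task); `force_col` can point at any other column, e.g. a squared
#' area-under-the-curve term for the actual-force sensitivity analysis. The
#' force slope is the participant's *force sensitivity*, the failure slope
#' their *failure sensitivity*.
#'
#' @param features One participant's feature rows (see
#'   [build_feature_matrix()]), containing `rating`, `failure`, `hand`, and
#'   the force predictor column.
#' @param force_col Name of the force predictor column
#'   (default `"target_force_sq"`).
#' @param k,max_iter,tol Huber IRLS settings (see [huber_irls()]).
#' @return An object of class `sensitivity_estimate`: a list with
#'   `participant_id`, `intercept`, `force_slope`, `failure_slope`,
#'   `hand_coefficient`, `iterations`, `converged`, `n_trials`.
#' @export
fit_participant_robust <- function(features, force_col = "target_force_sq",
                                   k = 1.345, max_iter = 50, tol = 1e-8) {
  if (nrow(features) < 8) {
    abort("Need at least 8 trials to estimate sensitivities.",
          class = "effortsens_domain_error")
  }
  if (!force_col %in% names(features)) {
    abort(paste0("Force predictor column '", force_col, "' not found."),
          class = "effortsens_domain_error")
  }
  if (length(unique(features$failure)) < 2) {
    abort(paste0(
      "Participant ", features$participant_id[1],
      " has a single outcome class; the failure predictor is constant ",
      "and the fit would be rank deficient."
    ), class = "effortsens_rank_error")
  }
  x <- cbind(
    `(Intercept)` = 1,
    force = features[[force_col]],
    failure = features$failure,
    hand = features$hand
  )
  fit <- huber_irls(x, features$rating, k = k, max_iter = max_iter, tol = tol)
  structure(
    list(
      participant_id = features$participant_id[1],
      intercept = unname(fit$coefficients[1]),
      force_slope = unname(fit$coefficients[2]),
      failure_slope = unname(fit$coefficients[3]),
      hand_coefficient = unname(fit$coefficients[4]),
      iterations = fit$iterations,
      converged = fit$converged,
      n_trials = nrow(features),
      force_col = force_col
    ),
    class = "sensitivity_estimate"
  )
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_estimate> %s: intercept %.2f, force slope %.2f, failure slope %.2f\n",
    x$participant_id, x$intercept, x$force_slope, x$failure_slope))
  invisible(x)
}

#' @rdname fit_participant_robust
#' @param x A `sensitivity_estimate`.
#' @param ... Unused.
#' @method tidy sensitivity_estimate
#' @export
tidy.sensitivity_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "force", "failure", "hand"),
    estimate = c(x$intercept, x$force_slope, x$failure_slope,
                 x$hand_coefficient)
  )
}

#' Estimate sensitivities for every participant in a cohort
#'
#' Maps [fit_participant_robust()] over a cohort feature table and returns a
#' tidy tibble of per-participant estimates. Participants whose fit fails
#' (e.g. a single outcome class that slipped past preprocessing) raise an
#' error unless `on_error = "drop"`.
#'
#' @param features Cohort feature table from [build_cohort_features()].
#' @param on_error `"abort"` (default) or `"drop"` failing participants.
#' @inheritParams fit_participant_robust
#' @return A tibble with one row per participant: `participant_id`,
#'   `intercept`, `force_slope`, `failure_slope`, `hand_coefficient`,
#'   `iterations`, `converged`, `n_trials`.
#' @export
fit_cohort_sensitivities <- function(features, force_col = "target_force_sq",
                                     k = 1.345, max_iter = 50, tol = 1e-8,
                                     on_error = c("abort", "drop")) {
  on_error <- match.arg(on_error)
  fits <- features |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map(function(rows) {
      tryCatch(
        fit_participant_robust(rows, force_col = force_col, k = k,
                               max_iter = max_iter, tol = tol),
        error = function(e) {
          if (on_error == "abort") stop(e) else NULL
        }
      )
    }) |>
    purrr::compact()
  purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      participant_id = f$participant_id,
      intercept = f$intercept,
      force_slope = f$force_slope,
      failure_slope = f$failure_slope,
      hand_coefficient = f$hand_coefficient,
      iterations = f$iterations,
      converged = f$converged,
      n_trials = f$n_trials
    )
  })
}
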