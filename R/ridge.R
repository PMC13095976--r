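#' Huber trial weights for the feature model
#'
#' First step of the two-step feature analysis: fit the full feature model
#' `rating ~ all features` by Huber M-estimation (on within-participant
#' standardised features) and return the final IRLS weights. Trials whose
#' standardised residual lies within the tuning constant get weight 1;
#' grosser trials get proportionally smaller weights. Because the residual
#' scale is re-estimated from the data (MAD), the weights are invariant to
#' rescaling the rating units.
#'
#' @param features One participant's feature rows.
#' @param feature_cols Feature column names (default [feature_columns()]).
#' @param k,max_iter,tol Huber IRLS settings.
#' @return Numeric vector of per-trial weights in (0, 1].
#' @export
huber_trial_weights <- function(features, feature_cols = feature_columns(),
                                k = 1.345, max_iter = 50, tol = 1e-8) {
  std <- standardise_features(features, feature_cols)
  if (nrow(std$x) < ncol(std$x) + 2) {
    abort("Need at least p + 2 trials to derive trial weights.",
          class = "effortsens_domain_error")
  }
  fit <- huber_irls(cbind(`(Intercept)` = 1, std$x), features$rating,
                    k = k, max_iter = max_iter, tol = tol)
  fit$weights
}

# z-score feature columns within one participant; constant columns are an
# error for the ridge path (they carry no within-participant information)
standardise_features <- function(features, feature_cols) {
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  if (any(sigma == 0)) {
    abort(paste0("Constant feature column(s) within participant: ",
                 paste(feature_cols[sigma == 0], collapse = ", ")),
          class = "effortsens_rank_error")
  }
  list(x = sweep(sweep(x, 2, mu), 2, sigma, "/"), mu = mu, sigma = sigma)
}

# weighted ridge solve with an unpenalised intercept, via the augmented
# least-squares route: rows sqrt(w) * [1 x] stacked over penalty rows
# sqrt(lambda) on the slope columns only, solved by QR. Returns the
# intercept followed by the slope coefficients.
ridge_solve <- function(x, y, w, lambda) {
  p <- ncol(x)
  x1 <- cbind(icpt = 1, x)
  pen <- cbind(0, sqrt(lambda) * diag(p))
  xa <- rbind(sqrt(w) * x1, pen)
  ya <- c(sqrt(w) * y, rep(0, p))
  stats::lm.fit(xa, ya)$coefficients
}

#' Cross-validated weighted ridge regression
#'
#' Second step of the feature analysis: with trial weights from
#' [huber_trial_weights()], fits a ridge regression of the standardised
#' rating on the standardised features, choosing the shrinkage parameter by
#' k-fold cross-validation at minimum weighted validation mean-squared
#' error, then refits on all rows at the selected lambda. Both features and
#' outcome are standardised within the participant, so the coefficients are
#' standardised betas; an unpenalised intercept absorbs the weighted mean
#' (it is 0 only when the weights are uniform). The ridge objective is
#' `sum_i w_i (y_i - b0 - x_i b)^2 + lambda * ||b||^2`. Fold assignment is a
#' seeded random partition.
#'
#' @param features One participant's feature rows.
#' @param weights Per-trial weights (e.g. from [huber_trial_weights()]).
#' @param feature_cols Feature column names.
#' @param lambda Shrinkage grid (default 50 log-spaced values in
#'   `[1e-3, 1e3]`).
#' @param k_folds Number of CV folds (default 10); must not exceed the
#'   number of rows.
#' @param seed Integer seed for the fold partition.
#' @param weighted_cv Use the trial weights in the validation MSE as well as
#'   in training (default `TRUE`; the weights encode trial reliability, not
#'   fold membership).
#' @return An object of class `ridge_fit`: list with `participant_id`,
#'   `intercept` (unpenalised), `coefficients` (named, standardised),
#'   `lambda` (selected), `cv` (tibble lambda x mean MSE), `weights`,
#'   `feature_sd`, `rating_sd`.
#' @export
fit_weighted_ridge_cv <- function(features, weights,
                                  feature_cols = feature_columns(),
                                  lambda = default_lambda_grid(),
                                  k_folds = 10, seed = 1,
                                  weighted_cv = TRUE) {
  n <- nrow(features)
  if (length(lambda) == 0 || any(lambda < 0)) {
    abort("`lambda` must be a nonempty nonnegative grid.",
          class = "effortsens_config_error")
  }
  if (k_folds > n) {
    abort("`k_folds` cannot exceed the number of trials.",
          class = "effortsens_config_error")
  }
  if (length(weights) != n || any(weights <= 0) || any(weights > 1 + 1e-12)) {
    abort("`weights` must be per-trial values in (0, 1].",
          class = "effortsens_domain_error")
  }
  std <- standardise_features(features, feature_cols)
  y_sd <- sd(features$rating)
  if (y_sd == 0) {
    abort("Ratings are constant within participant; nothing to model.",
          class = "effortsens_domain_error")
  }
  y <- (features$rating - mean(features$rating)) / y_sd
  x <- std$x

  folds <- withr::with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  mse <- matrix(NA_real_, nrow = length(lambda), ncol = k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    for (l in seq_along(lambda)) {
      b <- ridge_solve(x[tr, , drop = FALSE], y[tr], weights[tr], lambda[l])
      pred <- b[1] + drop(x[!tr, , drop = FALSE] %*% b[-1])
      err <- (y[!tr] - pred)^2
      mse[l, f] <- if (weighted_cv) {
        sum(weights[!tr] * err) / sum(weights[!tr])
      } else {
        mean(err)
      }
    }
  }
  cv_mean <- rowMeans(mse)
  best <- which.min(cv_mean)
  coefs <- ridge_solve(x, y, weights, lambda[best])
  structure(
    list(
      participant_id = features$participant_id[1],
      intercept = unname(coefs[1]),
      coefficients = setNames(coefs[-1], feature_cols),
      lambda = lambda[best],
      cv = tibble::tibble(lambda = lambda, mse = cv_mean),
      weights = weights,
      feature_sd = std$sigma,
      rating_sd = y_sd
    ),
    class = "ridge_fit"
  )
}

#' Default shrinkage grid for the ridge feature model
#' @return 50 log-spaced values between 1e-3 and 1e3.
#' @export
default_lambda_grid <- function() 10^seq(-3, 3, length.out = 50)

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> %s: lambda = %.4g\n", x$participant_id, x$lambda))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @rdname fit_weighted_ridge_cv
#' @param x A `ridge_fit`.
#' @param ... Unused.
#' @method tidy ridge_fit
#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_weighted_ridge_cv
#' @param object A `ridge_fit`.
#' @method glance ridge_fit
#' @export
glance.ridge_fit <- function(object, ...) {
  tibble::tibble(
    lambda = object$lambda,
    cv_mse = min(object$cv$mse),
    n_trials = length(object$weights)
  )
}

#' Two-step robust ridge for every participant
#'
#' Runs [huber_trial_weights()] then [fit_weighted_ridge_cv()] per
#' participant and returns a participant x feature table of standardised
#' betas.
#'
#' @param features Cohort feature table from [build_cohort_features()].
#' @inheritParams fit_weighted_ridge_cv
#' @inheritParams huber_trial_weights
#' @return A list of class `cohort_ridge`: `betas` (tibble, one row per
#'   participant with one column per feature plus `lambda`), `fits` (list of
#'   `ridge_fit`).
#' @export
fit_cohort_ridge <- function(features, feature_cols = feature_columns(),
                             lambda = default_lambda_grid(), k_folds = 10,
                             seed = 1, weighted_cv = TRUE, k = 1.345) {
  groups <- features |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split()
  fits <- purrr::map(groups, function(rows) {
    w <- huber_trial_weights(rows, feature_cols, k = k)
    fit_weighted_ridge_cv(rows, w, feature_cols, lambda = lambda,
                          k_folds = k_folds, seed = seed,
                          weighted_cv = weighted_cv)
  })
  betas <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(participant_id = f$participant_id,
                   !!!as.list(f$coefficients), lambda = f$lambda)
  })
  structure(list(betas = betas, fits = fits, feature_cols = feature_cols),
            class = "cohort_ridge")
}

#' @export
print.cohort_ridge <- function(x, ...) {
  cat(sprintf("<cohort_ridge> %d participants x %d features\n",
              nrow(x$betas), length(x$feature_cols)))
  invisible(x)
}

#' Group summary of ridge betas
#'
#' Across-participant mean standardised coefficient per feature with a
#' t-based 95% confidence interval.
#'
#' @param ridge A `cohort_ridge` (or its `betas` tibble).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `term`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_group <- function(ridge, conf_level = 0.95) {
  betas <- if (inherits(ridge, "cohort_ridge")) ridge$betas else ridge
  cols <- setdiff(names(betas), c("participant_id", "lambda"))
  if (nrow(betas) < 2) {
    abort("Need at least 2 participants to summarise.",
          class = "effortsens_domain_error")
  }
  purrr::map_dfr(cols, function(cl) {
    v <- betas[[cl]]
    n <- length(v)
    m <- mean(v)
    se <- sd(v) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    tibble::tibble(term = cl, mean = m,
                   ci_lo = m - tq * se, ci_hi = m + tq * se, n = n)
  })
}

#' Mean pairwise feature correlations across participants
#'
#' Computes each participant's Pearson correlation matrix over the feature
#' columns and averages them elementwise. A participant contributes `NA` to
#' entries involving a feature that is constant for them; such entries are
#' dropped from the mean for those participants.
#'
#' @param features Cohort feature table.
#' @param feature_cols Feature column names.
#' @return A symmetric matrix with unit diagonal.
#' @export
feature_correlations <- function(features, feature_cols = feature_columns()) {
  groups <- features |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split()
  if (length(groups) < 2 || any(vapply(groups, nrow, integer(1)) < 3)) {
    abort("Need >= 2 participants with >= 3 rows each.",
          class = "effortsens_domain_error")
  }
  mats <- lapply(groups, function(rows) {
    suppressWarnings(cor(as.matrix(rows[, feature_cols, drop = FALSE])))
  })
  arr <- simplify2array(mats)
  out <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  diag(out) <- 1
  out
}

#' Plot the group summary of ridge betas
#'
#' Dot-and-interval plot of the mean standardised coefficient per feature
#' across participants.
#'
#' @param object A `cohort_ridge`.
#' @param ... Unused.
#' @method autoplot cohort_ridge
#' @export
autoplot.cohort_ridge <- function(object, ...) {
  summ <- summarize_group(object)
  summ$term <- stats::reorder(summ$term, summ$mean)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardised ridge coefficient (mean, 95% CI)",
                  y = NULL, title = "Feature contributions to effort rating") +
    ggplot2::theme_minimal()
}
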