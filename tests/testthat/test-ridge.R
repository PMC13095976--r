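# closed-form oracle: solve the penalised weighted normal equations directly
# (intercept unpenalised); returns the slope coefficients
oracle_ridge <- function(x, y, w, lambda) {
  x1 <- cbind(1, x)
  pen <- diag(c(0, rep(1, ncol(x))))
  solve(t(x1) %*% (w * x1) + lambda * pen, t(x1) %*% (w * y))[-1, 1]
}

std_xy <- function(rows) {
  x <- scale(as.matrix(rows[, feature_columns()]))
  y <- drop(scale(rows$rating))
  list(x = x, y = y)
}

test_that("trial weights are 1 on exactly-linear data and downweight an outlier", {
  rows <- synthetic_feature_rows(noise_sd = 0)
  # ratings exactly linear in the feature columns: the Huber fit is exact
  rows$rating <- 5 + 30 * rows$target_force + 8 * rows$failure +
    2 * rows$hand + 0.2 * rows$cumulative_force
  expect_equal(huber_trial_weights(rows), rep(1, nrow(rows)))
  rows2 <- synthetic_feature_rows(noise_sd = 3, seed = 21)
  rows2$rating[9] <- rows2$rating[9] + 80
  w <- huber_trial_weights(rows2)
  expect_true(all(w > 0 & w <= 1))
  expect_equal(which.min(w), 9L)
  # rating-unit invariance (the residual scale is re-estimated)
  rows3 <- dplyr::mutate(rows2, rating = rating * 12.5)
  expect_equal(huber_trial_weights(rows3), w, tolerance = 1e-4)
  # duplicated feature -> rank deficiency, named
  rows4 <- dplyr::mutate(rows2, excess_force = cumulative_force)
  expect_error(huber_trial_weights(rows4), class = "effortsens_rank_error")
})

test_that("ridge at lambda = 0 equals weighted least squares", {
  rows <- synthetic_feature_rows(noise_sd = 3, seed = 22)
  w <- withr::with_seed(1, runif(nrow(rows), 0.5, 1))
  fit <- fit_weighted_ridge_cv(rows, w, lambda = 0, k_folds = 4, seed = 2)
  s <- std_xy(rows)
  wls <- coef(lm(s$y ~ s$x, weights = w))
  expect_equal(unname(fit$coefficients), unname(wls[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(wls[1]), tolerance = 1e-8)
})

test_that("the ridge solver matches the closed-form oracle at every grid point", {
  rows <- synthetic_feature_rows(noise_sd = 4, seed = 23)
  w <- huber_trial_weights(rows)
  s <- std_xy(rows)
  for (lam in default_lambda_grid()[c(1, 13, 25, 37, 50)]) {
    fit <- fit_weighted_ridge_cv(rows, w, lambda = lam, k_folds = 4, seed = 3)
    expect_equal(unname(fit$coefficients),
                 unname(oracle_ridge(s$x, s$y, w, lam)), tolerance = 1e-8)
  }
  # extreme shrinkage sends every coefficient to zero
  big <- fit_weighted_ridge_cv(rows, w, lambda = 1e9, k_folds = 4, seed = 3)
  expect_lt(max(abs(big$coefficients)), 1e-4)
})

test_that("cross-validation selects the MSE-minimising lambda reproducibly", {
  rows <- synthetic_feature_rows(noise_sd = 4, seed = 24)
  w <- huber_trial_weights(rows)
  a <- fit_weighted_ridge_cv(rows, w, seed = 7)
  b <- fit_weighted_ridge_cv(rows, w, seed = 7)
  expect_identical(a$lambda, b$lambda)
  expect_equal(a$coefficients, b$coefficients)
  expect_equal(a$lambda, a$cv$lambda[which.min(a$cv$mse)])
  expect_error(fit_weighted_ridge_cv(rows, w, k_folds = 100),
               class = "effortsens_config_error")
  expect_error(fit_weighted_ridge_cv(rows, w[-1]),
               class = "effortsens_domain_error")
})

test_that("standardised betas map back to the raw-scale fit at lambda = 0", {
  rows <- synthetic_feature_rows(noise_sd = 3, seed = 25)
  w <- withr::with_seed(2, runif(nrow(rows), 0.6, 1))
  fit <- fit_weighted_ridge_cv(rows, w, lambda = 0, k_folds = 4)
  raw <- coef(lm(
    stats::reformulate(feature_columns(), response = "rating"),
    data = rows, weights = w
  ))[feature_columns()]
  back <- fit$coefficients * fit$rating_sd / fit$feature_sd
  expect_equal(unname(back), unname(raw), tolerance = 1e-8)
})

test_that("group summaries and feature correlations behave structurally", {
  betas <- tibble::tibble(
    participant_id = c("a", "b", "c"),
    target_force = c(0.5, 0.5, 0.5),
    failure = c(0.1, 0.2, 0.3),
    lambda = 1
  )
  summ <- summarize_group(betas)
  expect_equal(summ$mean[summ$term == "target_force"], 0.5)
  expect_equal(summ$ci_lo[summ$term == "target_force"],
               summ$ci_hi[summ$term == "target_force"])
  feats <- dplyr::bind_rows(
    synthetic_feature_rows("a", noise_sd = 3, seed = 26),
    synthetic_feature_rows("b", noise_sd = 3, seed = 27)
  )
  fc <- feature_correlations(feats)
  expect_equal(fc, t(fc))
  expect_equal(unname(diag(fc)), rep(1, ncol(fc)))
  dup <- dplyr::mutate(feats, excess_force = target_force)
  fc2 <- feature_correlations(dup)
  expect_equal(fc2["excess_force", "target_force"], 1)
})
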