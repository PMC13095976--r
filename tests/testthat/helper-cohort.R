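# Shared fixtures, all generated in code.

# task design with reduced sampling rate: outcome probabilities are rate-
# insensitive, and simulation time drops ~5x relative to 250 Hz
fast_design <- function(rate = 50) task_design(sample_rate_hz = rate)

# population used for the link-recovery study: ratings stay clear of the
# scale ceiling so the force-to-rating curvature is not censored
recovery_population <- function() {
  cohort_population(
    intercept_mean = 8, intercept_sd = 4,
    force_sens_mean = 60, force_sens_sd = 12,
    failure_sens_mean = 5, failure_sens_sd = 4,
    rating_noise_sd = 5
  )
}

# noiseless participant: deterministic traces and ratings
exact_profile <- function(...) {
  participant_profile(motor_noise_scale = 0, rating_noise_sd = 0, ...)
}

# feature rows with known generative coefficients; traces constant at the
# target (so AUC tracks target exactly), outcomes assigned by hand
synthetic_feature_rows <- function(id = "S1",
                                   intercept = 10, force_slope = 60,
                                   failure_slope = 8, hand_coef = 2,
                                   noise_sd = 0, n_rep = 4, seed = 1,
                                   rate = 50) {
  withr::with_seed(seed, {
    f <- rep(c(0.2, 0.4, 0.6, 0.8, 1.0), each = n_rep)
    # failures concentrate at the high force levels; hands alternate,
    # so failure, hand and squared force are mutually non-collinear
    fail <- as.integer(f >= 0.8)
    hand <- rep(c(0L, 1L), length.out = length(f))
    rating <- intercept + force_slope * f^2 + failure_slope * fail +
      hand_coef * hand + rnorm(length(f), 0, noise_sd)
    tibble::tibble(
      participant_id = id,
      trial_index = seq_along(f),
      rating = rating,
      target_force = f,
      target_force_sq = f^2,
      failure = fail,
      rating_lag1 = dplyr::lag(rating, default = 0),
      target_lag1 = dplyr::lag(f, default = 0),
      cumulative_force = cumsum(f * 6.5),
      coefficient_of_variation = runif(length(f), 0.01, 0.05),
      initial_force_difference = rnorm(length(f), 0, 0.05),
      excess_force = rnorm(length(f), 0.5, 0.2),
      auc = f * 6.5,
      hand = hand
    )
  })
}

# participants table with chosen MVC ratios, for exclusion-rule tests
ratio_participants <- function(ratios) {
  n <- length(ratios)
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    age = 25 + seq_len(n) %% 10, sex = seq_len(n) %% 2,
    dominant_hand = "right",
    mvc_dom = 300 * ratios, mvc_nondom = 300,
    phq9 = 5L, aes = 30L
  )
}
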