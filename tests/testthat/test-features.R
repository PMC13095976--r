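test_that("area under the curve is the trapezoidal integral", {
  rate <- 250
  expect_equal(area_under_curve(force_trace(rep(0.5, 4 * rate + 1), rate)), 2)
  expect_equal(area_under_curve(force_trace(rep(0, 100), rate)), 0)
  ramp <- seq(0, 1, length.out = 2 * rate + 1)  # 0 -> 1 over 2 s
  expect_equal(area_under_curve(force_trace(ramp, rate)), 1)
  expect_error(area_under_curve(force_trace(0.5, rate)),
               class = "effortsens_domain_error")
})

test_that("trapezoidal AUC matches the analytic integral of a smooth trace", {
  rate <- 250
  t <- seq(0, 4, by = 1 / rate)
  x <- 0.5 + 0.2 * sin(2 * pi * t / 4)
  tr <- force_trace(x, rate)
  analytic <- 0.5 * 4  # the sine integrates to zero over one full period
  expect_equal(area_under_curve(tr), analytic, tolerance = 1e-6)
})

test_that("coefficient of variation uses the sample SD convention", {
  expect_equal(coefficient_of_variation(force_trace(c(1, 3), 10)),
               sqrt(2) / 2)
  expect_equal(coefficient_of_variation(force_trace(rep(0.4, 50), 10)), 0)
  x <- runif(40, 0.2, 0.8)
  expect_equal(coefficient_of_variation(force_trace(x, 10)),
               coefficient_of_variation(force_trace(3.7 * x, 10)))
  expect_warning(cv0 <- coefficient_of_variation(force_trace(rep(0, 5), 10)))
  expect_true(is.na(cv0))
})

test_that("initial peak detection finds the first qualifying local maximum", {
  tr <- force_trace(c(0, 0.5, 0.3, 0.6, 0.2), 10)
  pk <- detect_initial_peak(tr)
  expect_equal(pk$peak, 0.5)
  expect_false(pk$fallback)
  # sub-threshold first peak is skipped
  tr2 <- force_trace(c(0, 0.05, 0.02, 0.4, 0.1), 10)
  expect_equal(detect_initial_peak(tr2, min_height = 0.1)$peak, 0.4)
  # monotone trace: global-maximum fallback, flagged
  tr3 <- force_trace(seq(0, 1, length.out = 20), 10)
  pk3 <- detect_initial_peak(tr3)
  expect_equal(pk3$peak, 1)
  expect_true(pk3$fallback)
  # signed overshoot
  expect_equal(initial_force_difference(tr, 0.4), 0.1)
  expect_equal(initial_force_difference(tr, 0.5), 0)
  expect_equal(initial_force_difference(tr, 0.6), -0.1)
})

test_that("excess force compares the AUC with the ideal 3-s hold area", {
  rate <- 50
  at_target_3s <- force_trace(rep(0.4, 3 * rate + 1), rate)
  expect_equal(excess_force(at_target_3s, 0.4), 0)
  at_target_6s <- force_trace(rep(0.4, 6 * rate + 1), rate)
  expect_equal(excess_force(at_target_6s, 0.4), 0.4 * 3)
  half_target <- force_trace(rep(0.2, 3 * rate + 1), rate)
  expect_equal(excess_force(half_target, 0.4), -0.4 * 1.5)
})

test_that("cumulative force accumulates per-trial AUCs inclusively", {
  rate <- 25
  traces <- lapply(c(0.2, 0.4, 0.6), function(f) {
    force_trace(rep(f, 2 * rate + 1), rate)
  })
  trials <- tibble::tibble(trial_index = 1:3, trace = traces)
  aucs <- vapply(traces, area_under_curve, numeric(1))
  expect_equal(cumulative_force(trials, 1), aucs[1])
  expect_equal(cumulative_force(trials, 3), sum(aucs))
  vals <- vapply(1:3, function(i) cumulative_force(trials, i), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(cumulative_force(trials, 4), class = "effortsens_domain_error")
})

test_that("the feature matrix drops the lag-undefined first trial", {
  coh <- generate_cohort(2, design = fast_design(25), seed = 4)
  one <- dplyr::filter(coh$trials, participant_id == "P001")
  fm <- build_feature_matrix(one)
  expect_equal(nrow(fm), 37L)
  expect_equal(fm$rating_lag1, one$rating[-38])
  expect_equal(fm$target_lag1, one$target_force_frac[-38])
  # column-wise oracle recomputation
  i <- 10  # feature row 10 corresponds to trial 11
  expect_equal(fm$auc[i], area_under_curve(one$trace[[i + 1]]))
  expect_equal(fm$coefficient_of_variation[i],
               coefficient_of_variation(one$trace[[i + 1]]))
  expect_equal(fm$cumulative_force[i],
               cumulative_force(one, i + 1))
  expect_equal(fm$excess_force[i],
               excess_force(one$trace[[i + 1]], one$target_force_frac[i + 1],
                            required_hold_s = 3))
  expect_equal(fm$initial_force_difference[i],
               initial_force_difference(one$trace[[i + 1]],
                                        one$target_force_frac[i + 1]))
  expect_equal(fm$hand, as.integer(one$hand[-1] == "nondominant"))
  expect_true(all(is.finite(as.matrix(fm[, feature_columns()]))))
  # a missing trace is reported by trial index
  broken <- one
  broken$trace[5] <- list(NULL)
  expect_error(build_feature_matrix(broken), "5",
               class = "effortsens_domain_error")
})
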