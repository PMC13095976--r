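test_that("rating generation is the clipped quadratic-plus-failure rule", {
  p <- participant_profile(rating_intercept = 10, force_sensitivity_true = 60,
                           failure_sensitivity_true = 5, rating_noise_sd = 0)
  expect_equal(generate_rating(p, 0.5, 0), 25)
  expect_equal(generate_rating(p, 0.5, 1), 30)
  hi <- participant_profile(rating_intercept = 95, force_sensitivity_true = 60,
                            rating_noise_sd = 0)
  expect_equal(generate_rating(hi, 1.0, 0), 100)  # clipped at the scale top
  noisy <- participant_profile(rating_noise_sd = 40)
  r <- vapply(1:50, function(i) generate_rating(noisy, 0.8, 1, seed = i),
              numeric(1))
  expect_true(all(r >= 0 & r <= 100))
  expect_identical(generate_rating(noisy, 0.5, 0, seed = 4),
                   generate_rating(noisy, 0.5, 0, seed = 4))
  expect_error(generate_rating(p, 0.5, 2), class = "effortsens_domain_error")
})

test_that("cohorts are byte-identical under equal seeds", {
  d <- fast_design(25)
  a <- generate_cohort(3, design = d, seed = 21)
  b <- generate_cohort(3, design = d, seed = 21)
  expect_identical(a$participants, b$participants)
  expect_identical(dplyr::select(a$trials, -trace),
                   dplyr::select(b$trials, -trace))
  expect_identical(a$trials$trace[[10]]$samples, b$trials$trace[[10]]$samples)
  c_ <- generate_cohort(3, design = d, seed = 22)
  expect_false(identical(a$participants$mvc_dom, c_$participants$mvc_dom))
})

test_that("cohort trials respect the schedule invariants", {
  coh <- generate_cohort(4, design = fast_design(25), seed = 2)
  per <- split(coh$trials, coh$trials$participant_id)
  for (tr in per) {
    expect_equal(nrow(tr), 38L)
    expect_true(all(tr$hand[-1] != tr$hand[-38]))
    expect_true(all(tr$rating >= 0 & tr$rating <= 100))
    expect_true(all(tr$outcome %in% 0:1))
  }
  expect_true(all(c("phq9", "aes", "sim_force_sensitivity") %in%
                    names(coh$participants)))
  expect_true(all(coh$participants$phq9 >= 0 & coh$participants$phq9 <= 27))
  expect_true(all(coh$participants$aes >= 18 & coh$participants$aes <= 72))
})

test_that("symptom couplings propagate to the questionnaire scores", {
  d <- fast_design(25)
  neg <- generate_cohort(
    200, design = d, seed = 31,
    coupling = cohort_coupling(force_slope_vs_symptom = -0.5,
                               failure_slope_vs_symptom = 0.5)
  )$participants
  expect_lt(cor(neg$sim_force_sensitivity, neg$phq9), -0.3)
  expect_gt(cor(neg$sim_failure_sensitivity, neg$phq9), 0.3)

  null <- generate_cohort(
    200, design = d, seed = 32,
    coupling = cohort_coupling(0, 0, 0)
  )$participants
  expect_lte(abs(cor(null$sim_force_sensitivity, null$phq9)), 0.2)
  expect_error(cohort_coupling(force_slope_vs_symptom = -1.5),
               class = "effortsens_config_error")
  expect_error(generate_cohort(1, design = d, seed = 1),
               class = "effortsens_config_error")
})

test_that("miscalibration relabelling inverts the force correction exactly", {
  coh <- generate_cohort(6, design = fast_design(25), seed = 8)
  mis <- apply_miscalibration(coh)
  # equal MVCs leave targets unchanged
  eq <- coh
  eq$participants$mvc_nondom <- eq$participants$mvc_dom
  expect_equal(apply_miscalibration(eq)$trials$target_force_frac,
               eq$trials$target_force_frac, tolerance = 1e-14)
  # round trip restores the experienced fractions
  back <- correct_target_forces(mis$trials, mis$participants)
  expect_equal(back$target_force_frac, coh$trials$target_force_frac,
               tolerance = 1e-12)
  expect_equal(back$band_lo, coh$trials$band_lo, tolerance = 1e-12)
})

test_that("miscalibrated generation logs nominal but behaves at experienced forces", {
  coh <- generate_cohort(5, design = fast_design(25), seed = 13,
                         miscalibrate = TRUE)
  # logged targets are the five nominal levels
  expect_setequal(unique(coh$trials$target_force_frac),
                  c(0.2, 0.4, 0.6, 0.8, 1.0))
  # corrected targets recover the experienced fractions (continuous values)
  fixed <- correct_target_forces(coh$trials, coh$participants)
  r <- coh$participants$mvc_dom / coh$participants$mvc_nondom
  names(r) <- coh$participants$id
  expected <- coh$trials$target_force_frac *
    ifelse(coh$trials$hand == "dominant",
           1 / r[coh$trials$participant_id], r[coh$trials$participant_id])
  expect_equal(fixed$target_force_frac, unname(expected), tolerance = 1e-12)
})
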