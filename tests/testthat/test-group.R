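# independent step-up oracle: q_(i) = min_{j >= i} m * p_(j) / j, by
# explicit enumeration over the sorted positions
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (ii in seq_len(m)) {
    cand <- vapply(ii:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[ii]] <- min(cand, 1)
  }
  q
}

test_that("Benjamini-Hochberg matches brute-force step-up on 4-value families", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  withr::with_seed(42, {
    base <- runif(4)
    idx <- unlist(lapply(1:4, function(k) combn(4, k, simplify = FALSE)),
                  recursive = FALSE)
    for (ix in idx) {
      p <- base[ix]
      expect_equal(benjamini_hochberg(p), brute_bh(p))
    }
  })
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "effortsens_domain_error")
  expect_error(benjamini_hochberg(c(NA, 0.5)), class = "effortsens_domain_error")
})

make_group_data <- function(n = 40, seed = 9) {
  withr::with_seed(seed, {
    latent <- rnorm(n)
    participants <- tibble::tibble(
      id = sprintf("G%03d", 1:n),
      age = round(rnorm(n, 28, 5)),
      sex = rbinom(n, 1, 0.5),
      phq9 = pmax(pmin(round(6 + 3 * latent + rnorm(n)), 27), 0),
      aes = pmax(pmin(round(31 + 5 * rnorm(n)), 72), 18),
      mvc_dom = rnorm(n, 350, 60),
      mvc_nondom = rnorm(n, 330, 60)
    )
    estimates <- tibble::tibble(
      participant_id = participants$id,
      intercept = 10 + 4 * latent + rnorm(n),
      force_slope = 70 - 10 * latent + rnorm(n, 0, 3),
      failure_slope = 8 + 4 * latent + rnorm(n, 0, 2)
    )
    list(participants = participants, estimates = estimates)
  })
}

test_that("the group regression reports standardised coefficients with one FDR family", {
  d <- make_group_data()
  gm <- fit_group_regression(d$estimates, d$participants)
  tab <- tibble::as_tibble(gm)
  expect_setequal(unique(tab$outcome), c("force_slope", "failure_slope"))
  fam <- tab[!is.na(tab$q_value), ]
  expect_equal(nrow(fam), 4L)
  expect_setequal(fam$term, c("phq9", "aes"))
  expect_true(all(fam$q_value >= fam$p_value - 1e-12))
  expect_lt(tab$estimate[tab$outcome == "force_slope" & tab$term == "phq9"], 0)
  expect_gt(tab$estimate[tab$outcome == "failure_slope" & tab$term == "phq9"], 0)
})

test_that("the group regression is equivariant to affine covariate rescaling", {
  d <- make_group_data(seed = 10)
  gm1 <- fit_group_regression(d$estimates, d$participants)
  resc <- dplyr::mutate(d$participants,
                        phq9 = 10 * phq9 + 3, age = age / 7,
                        mvc_dom = mvc_dom * 2, mvc_nondom = mvc_nondom * 2)
  gm2 <- fit_group_regression(d$estimates, resc)
  expect_equal(tibble::as_tibble(gm1)$estimate,
               tibble::as_tibble(gm2)$estimate, tolerance = 1e-10)
})

test_that("duplicating every participant keeps estimates and shrinks p-values", {
  d <- make_group_data(seed = 11)
  gm1 <- tibble::as_tibble(fit_group_regression(d$estimates, d$participants))
  dup_est <- dplyr::bind_rows(
    d$estimates,
    dplyr::mutate(d$estimates, participant_id = paste0(participant_id, "b"))
  )
  dup_par <- dplyr::bind_rows(
    d$participants,
    dplyr::mutate(d$participants, id = paste0(id, "b"))
  )
  gm2 <- tibble::as_tibble(fit_group_regression(dup_est, dup_par))
  # coefficients on z-scored variables are exactly invariant; the intercept
  # and the 0/1 sex code pick up the sample-sd (n - 1) factor only
  zterms <- gm1$term %in% c("phq9", "aes", "age", "mvc_ratio")
  expect_equal(gm1$estimate[zterms], gm2$estimate[zterms], tolerance = 1e-10)
  expect_equal(gm1$estimate, gm2$estimate, tolerance = 0.01)
  slope_terms <- gm1$term != "(Intercept)"
  expect_true(all(gm2$p_value[slope_terms] <= gm1$p_value[slope_terms] + 1e-12))
  # constant covariate is named in the error
  const <- dplyr::mutate(d$participants, aes = 30L)
  expect_error(fit_group_regression(d$estimates, const), "aes",
               class = "effortsens_domain_error")
})

test_that("the intercept-symptom correlation reflects the built-in coupling", {
  coh <- generate_cohort(
    30, design = fast_design(25), seed = 55,
    coupling = cohort_coupling(intercept_vs_symptom = 0.7)
  )
  feats <- build_cohort_features(coh)
  res <- intercept_symptom_analysis(feats, coh$participants)
  expect_gt(res$r, 0)
  # rating_cap = 100 is the identity analysis
  res_cap100 <- intercept_symptom_analysis(feats, coh$participants,
                                           rating_cap = 100)
  expect_equal(res$r, res_cap100$r)
  expect_error(intercept_symptom_analysis(feats, coh$participants,
                                          rating_cap = 0),
               class = "effortsens_domain_error")
})

test_that("trimming near-ceiling trials barely moves r in a no-ceiling cohort", {
  coh <- generate_cohort(
    30, design = fast_design(25), seed = 56,
    coupling = cohort_coupling(intercept_vs_symptom = 0.5),
    population = cohort_population(intercept_mean = 8, intercept_sd = 3,
                                   force_sens_mean = 45, force_sens_sd = 8,
                                   failure_sens_mean = 4, failure_sens_sd = 3,
                                   rating_noise_sd = 4)
  )
  feats <- build_cohort_features(coh)
  expect_lt(max(feats$rating), 90)  # genuinely no trials near the cap
  r_full <- intercept_symptom_analysis(feats, coh$participants)$r
  r_cap <- intercept_symptom_analysis(feats, coh$participants,
                                      rating_cap = 90)$r
  expect_lt(abs(r_full - r_cap), 0.05)
})

test_that("AUC-based sensitivities mirror target-based ones when traces track targets", {
  feats <- dplyr::bind_rows(lapply(1:8, function(i) {
    synthetic_feature_rows(sprintf("T%02d", i),
                           force_slope = 40 + 5 * i,
                           noise_sd = 2, seed = 400 + i)
  }))
  target_based <- fit_cohort_sensitivities(feats)
  auc_based <- actual_force_sensitivity(feats)
  m <- dplyr::inner_join(target_based, auc_based, by = "participant_id",
                         suffix = c("_t", "_a"))
  expect_gt(cor(m$force_slope_t, m$force_slope_a), 0.9)
  expect_equal(rank(m$force_slope_t), rank(m$force_slope_a))
  expect_error(actual_force_sensitivity(dplyr::select(feats, -auc)),
               class = "effortsens_domain_error")
})
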