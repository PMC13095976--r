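test_that("force correction applies the cross-hand MVC formulas", {
  p <- tibble::tibble(id = "P1", mvc_dom = 400, mvc_nondom = 300)
  tr <- tibble::tibble(
    participant_id = "P1",
    hand = c("dominant", "nondominant"),
    target_force_frac = c(0.40, 0.80),
    band_lo = c(0.38, 0.76), band_hi = c(0.42, 0.84)
  )
  out <- correct_target_forces(tr, p)
  expect_equal(out$target_force_frac, c(0.40 * 300 / 400, 0.80 * 400 / 300))
  expect_equal(out$band_lo, c(0.38 * 0.75, 0.76 * 4 / 3))
  # equal MVCs: identity
  p2 <- tibble::tibble(id = "P1", mvc_dom = 350, mvc_nondom = 350)
  expect_equal(correct_target_forces(tr, p2)$target_force_frac,
               tr$target_force_frac)
  # degenerate MVCs rejected
  p3 <- tibble::tibble(id = "P1", mvc_dom = 0, mvc_nondom = 300)
  expect_error(correct_target_forces(tr, p3), class = "effortsens_domain_error")
  expect_error(
    correct_target_forces(dplyr::mutate(tr, participant_id = "P9"), p),
    class = "effortsens_domain_error"
  )
})

test_that("MVC ratio is dominant over nondominant", {
  p <- tibble::tibble(id = c("a", "b", "c"),
                      mvc_dom = c(400, 350, 300),
                      mvc_nondom = c(300, 350, 400))
  expect_equal(compute_mvc_ratio(p)$mvc_ratio, c(4 / 3, 1, 0.75))
  expect_error(compute_mvc_ratio(tibble::tibble(id = "x", mvc_dom = 1,
                                                mvc_nondom = 0)),
               class = "effortsens_domain_error")
})

test_that("top-quartile exclusion removes floor(n/4) largest ratios", {
  # 8 distinct ratios: the 2 largest go
  p8 <- ratio_participants(seq(0.8, 1.5, length.out = 8))
  q8 <- exclude_top_quartile_ratio(p8)
  expect_equal(nrow(q8$retained), 6L)
  expect_setequal(q8$excluded, p8$id[7:8])
  # 108 distinct ratios retain exactly 81
  p108 <- ratio_participants(seq(0.7, 1.77, length.out = 108))
  expect_equal(nrow(exclude_top_quartile_ratio(p108)$retained), 81L)
  # all ties: still remove n/4, by stable id order
  peq <- ratio_participants(rep(1.1, 8))
  qeq <- exclude_top_quartile_ratio(peq)
  expect_equal(nrow(qeq$retained), 6L)
  expect_equal(qeq$excluded, peq$id[1:2])
  expect_true(qeq$tie_at_boundary)
  expect_error(exclude_top_quartile_ratio(peq[1:3, ]),
               class = "effortsens_domain_error")
})

test_that("per-participant Spearman correlation uses average ranks", {
  tr <- tibble::tibble(
    participant_id = "P1",
    target_force_frac = c(1, 2, 3, 4),
    rating = c(10, 30, 20, 40)
  )
  expect_equal(spearman_force_rating(tr)$spearman_rho, 0.8)
  up <- dplyr::mutate(tr, rating = c(1, 2, 3, 4))
  expect_equal(spearman_force_rating(up)$spearman_rho, 1.0)
  dn <- dplyr::mutate(tr, rating = c(4, 3, 2, 1))
  expect_equal(spearman_force_rating(dn)$spearman_rho, -1.0)
  flat <- dplyr::mutate(tr, rating = 5)
  expect_true(is.na(spearman_force_rating(flat)$spearman_rho))
  expect_false(spearman_force_rating(flat)$rho_defined)
})

# builds a deterministic trial table for one participant: a monotone
# force-rating profile with a controllable number of failures
toy_trials <- function(id, n_fail = 10, rho_break = FALSE) {
  f <- rep(c(0.2, 0.4, 0.6, 0.8, 1.0), each = 6)
  rating <- if (rho_break) 100 - 80 * f else 10 + 80 * f
  tibble::tibble(
    participant_id = id, trial_index = seq_along(f),
    target_force_frac = f, rating = rating,
    outcome = c(rep(1L, n_fail), rep(0L, length(f) - n_fail))
  )
}

test_that("outlier exclusions flag planted outliers and all-success", {
  ids <- sprintf("Q%02d", 1:12)
  trials <- dplyr::bind_rows(
    purrr::map(ids[1:10], toy_trials, n_fail = 10),
    toy_trials(ids[11], n_fail = 10, rho_break = TRUE),  # rho = -1 outlier
    toy_trials(ids[12], n_fail = 0)                      # all-success
  )
  parts <- ratio_participants(rep(1, 12)) |>
    dplyr::mutate(id = ids)
  res <- apply_outlier_exclusions(trials, parts)
  rep_tab <- res$report
  expect_true(rep_tab$spearman_outlier[rep_tab$participant_id == ids[11]])
  expect_true(rep_tab$all_success[rep_tab$participant_id == ids[12]])
  expect_setequal(res$retained$id, ids[1:10])
  # homogeneous cohort: nobody excluded; zero-SD criteria disabled, logged
  res2 <- apply_outlier_exclusions(
    dplyr::bind_rows(purrr::map(ids[1:10], toy_trials, n_fail = 10)),
    parts[1:10, ]
  )
  expect_equal(nrow(res2$retained), 10L)
  expect_true(res2$thresholds$spearman_sd_degenerate)
})

test_that("preprocessing counts reconcile and the chain is idempotent", {
  coh <- generate_cohort(16, design = fast_design(25), seed = 77,
                         miscalibrate = TRUE)
  prep <- preprocess_cohort(coh)
  cnt <- prep$counts
  expect_equal(unname(cnt["input"]), 16)
  expect_equal(unname(cnt["after_quartile"]), 16 - floor(16 / 4))
  expect_lte(cnt["after_outliers"], cnt["after_quartile"])
  expect_equal(sum(prep$exclusions$excluded),
               unname(cnt["input"] - cnt["after_outliers"]))
  expect_true(all(prep$exclusions$quartile_excluded[prep$exclusions$excluded] |
                    prep$exclusions$spearman_outlier[prep$exclusions$excluded] |
                    prep$exclusions$spearman_undefined[prep$exclusions$excluded] |
                    prep$exclusions$failure_outlier[prep$exclusions$excluded] |
                    prep$exclusions$all_success[prep$exclusions$excluded]))
  # re-running on the retained cohort removes no one at the outlier stage:
  # the criteria were defined on this very snapshot
  again <- apply_outlier_exclusions(prep$cohort$trials,
                                    prep$cohort$participants)
  expect_equal(nrow(again$retained), nrow(prep$cohort$participants))
})
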