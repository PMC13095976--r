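#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to `stats::p.adjust(method = "BH")` after validating the
#' inputs).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length; `q >= p` elementwise.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "effortsens_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot z-score a constant variable.", class = "effortsens_domain_error")
  }
  (x - mean(x)) / s
}

#' Second-level regression of sensitivities on symptom scores
#'
#' Fits two multiple linear regressions with each participant's force
#' sensitivity and failure sensitivity as the dependent variables and PHQ9
#' (depressive symptoms), AES (apathy), sex, age, and the MVC ratio as
#' predictors. All continuous variables (both outcomes, PHQ9, AES, age, MVC
#' ratio) are z-scored before fitting, so the reported coefficients are
#' standardised; sex enters as its 0/1 code. The four symptom coefficients
#' (PHQ9 and AES predicting each sensitivity) form one Benjamini-Hochberg
#' FDR family.
#'
#' @param estimates Tibble from [fit_cohort_sensitivities()].
#' @param participants Participant table with `id`, `phq9`, `aes`, `sex`,
#'   `age`, and `mvc_ratio` (computed if absent).
#' @return An object of class `group_model`: a tibble with one row per
#'   (outcome, term): `outcome`, `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `q_value` (symptom terms only), plus attribute
#'   `n`.
#' @export
fit_group_regression <- function(estimates, participants) {
  if (!"mvc_ratio" %in% names(participants)) {
    participants <- compute_mvc_ratio(participants)
  }
  dat <- dplyr::inner_join(estimates, participants,
                           by = c(participant_id = "id"))
  if (nrow(dat) < 10) {
    abort("Need at least 10 participants for the group regression.",
          class = "effortsens_domain_error")
  }
  for (v in c("phq9", "aes", "age", "mvc_ratio")) {
    if (sd(dat[[v]]) == 0) {
      abort(paste0("Covariate '", v, "' is constant; cannot z-score."),
            class = "effortsens_domain_error")
    }
  }
  X <- data.frame(
    phq9 = zscore(dat$phq9),
    aes = zscore(dat$aes),
    sex = dat$sex,
    age = zscore(dat$age),
    mvc_ratio = zscore(dat$mvc_ratio)
  )
  one_outcome <- function(y, label) {
    fit <- lm(zscore(y) ~ phq9 + aes + sex + age + mvc_ratio, data = X)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      outcome = label,
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      statistic = unname(sm[, "t value"]),
      p_value = unname(sm[, "Pr(>|t|)"])
    )
  }
  res <- dplyr::bind_rows(
    one_outcome(dat$force_slope, "force_slope"),
    one_outcome(dat$failure_slope, "failure_slope")
  )
  # FDR family: PHQ9 and AES predicting each of the two sensitivities
  fam <- res$term %in% c("phq9", "aes")
  res$q_value <- NA_real_
  res$q_value[fam] <- benjamini_hochberg(res$p_value[fam])
  structure(res, class = c("group_model", class(res)), n = nrow(dat))
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> n = %d participants\n", attr(x, "n")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @rdname fit_group_regression
#' @param x A `group_model`.
#' @param ... Unused.
#' @method tidy group_model
#' @export
tidy.group_model <- function(x, ...) tibble::as_tibble(x)

#' @rdname fit_group_regression
#' @method glance group_model
#' @export
glance.group_model <- function(x, ...) {
  tab <- tibble::as_tibble(x)
  sym <- tab[!is.na(tab$q_value), ]
  tibble::tibble(
    n = attr(x, "n"),
    n_terms = nrow(tab),
    n_fdr_family = nrow(sym),
    n_fdr_significant = sum(sym$q_value <= 0.05)
  )
}

#' Intercept-symptom correlation and rating-ceiling sensitivity analysis
#'
#' Pearson correlation between depressive-symptom scores and the robust
#' rating intercepts. When `rating_cap` is below the top of the scale, intercepts
#' are re-estimated after discarding trials whose rating exceeds the cap
#' (guarding against rating-ceiling compression driving the association) and
#' the correlation is recomputed on the re-estimated intercepts.
#'
#' @param features Cohort feature table from [build_cohort_features()].
#' @param participants Participant table with `id` and `phq9`.
#' @param rating_cap Keep trials with `rating <= rating_cap` (default 100,
#'   i.e. no trimming).
#' @param force_col,k,max_iter,tol Passed to [fit_cohort_sensitivities()]
#'   for the (re-)estimation.
#' @return A list with `r` (correlation), `p_value`, `n`, `rating_cap`, and
#'   the intercept table used.
#' @export
intercept_symptom_analysis <- function(features, participants,
                                       rating_cap = 100,
                                       force_col = "target_force_sq",
                                       k = 1.345, max_iter = 50, tol = 1e-8) {
  if (rating_cap <= 0 || rating_cap > 100) {
    abort("`rating_cap` must lie in (0, 100].", class = "effortsens_domain_error")
  }
  feats <- if (rating_cap < 100) {
    dplyr::filter(features, .data$rating <= rating_cap)
  } else {
    features
  }
  est <- fit_cohort_sensitivities(feats, force_col = force_col, k = k,
                                  max_iter = max_iter, tol = tol,
                                  on_error = "drop")
  dat <- dplyr::inner_join(est, participants, by = c(participant_id = "id"))
  if (nrow(dat) < 3) {
    abort("Need at least 3 participants for the intercept correlation.",
          class = "effortsens_domain_error")
  }
  ct <- stats::cor.test(dat$phq9, dat$intercept)
  list(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(dat),
    rating_cap = rating_cap,
    intercepts = dplyr::select(dat, "participant_id", "intercept", "phq9")
  )
}

#' Sensitivity to the actual force exerted
#'
#' Repeats the per-participant robust sensitivity estimation with the squared
#' per-trial area under the force curve (a proxy for the force actually
#' exerted) replacing the squared target force.
#'
#' @param features Cohort feature table containing an `auc` column.
#' @inheritParams fit_cohort_sensitivities
#' @return A tibble as from [fit_cohort_sensitivities()], with the force
#'   slope measured per squared AUC unit.
#' @export
actual_force_sensitivity <- function(features, k = 1.345, max_iter = 50,
                                     tol = 1e-8, on_error = c("abort", "drop")) {
  if (!"auc" %in% names(features)) {
    abort("`features` must carry an `auc` column (see build_feature_matrix()).",
          class = "effortsens_domain_error")
  }
  features$auc_sq <- features$auc^2
  fit_cohort_sensitivities(features, force_col = "auc_sq", k = k,
                           max_iter = max_iter, tol = tol,
                           on_error = match.arg(on_error))
}
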