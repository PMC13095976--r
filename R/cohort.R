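#' Construct a participant profile
#'
#' Holds one simulated participant's covariates, per-hand maximal voluntary
#' contraction (MVC), symptom scores, and the generative parameters that drive
#' their trial-level behaviour. The generative parameters are the latent
#' counterparts of the quantities the analysis estimates: the rating intercept,
#' the force sensitivity (rating units per squared force fraction), and the
#' failure sensitivity (rating units added on failed trials).
#'
#' @param id Participant label.
#' @param age Age in years.
#' @param sex Binary code (1 = female, 0 = male).
#' @param dominant_hand `"right"` or `"left"`.
#' @param mvc_dom,mvc_nondom Maximal voluntary contraction per hand, in
#'   newtons; both must be positive.
#' @param latent_symptom Standard-normal latent symptom severity; drives the
#'   questionnaire scores and (through the cohort couplings) the sensitivities.
#' @param phq9 Depressive-symptom score, integer 0--27.
#' @param aes Apathy score, integer 18--72.
#' @param rating_intercept Baseline effort rating, within the rating scale.
#' @param force_sensitivity_true Rating units per squared fraction-of-MVC.
#' @param failure_sensitivity_true Rating units added when a trial fails.
#' @param motor_noise_scale Nonnegative multiplier on all motor noise sources
#'   (see [simulate_force_trace()]); 0 gives noise-free traces.
#' @param rating_noise_sd Standard deviation of the Gaussian rating noise.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(id = "p1", age = 28, sex = 0L,
                                dominant_hand = "right",
                                mvc_dom = 350, mvc_nondom = 330,
                                latent_symptom = 0,
                                phq9 = 6L, aes = 31L,
                                rating_intercept = 10,
                                force_sensitivity_true = 70,
                                failure_sensitivity_true = 8,
                                motor_noise_scale = 1,
                                rating_noise_sd = 7) {
  if (mvc_dom <= 0 || mvc_nondom <= 0) {
    abort("MVC must be positive for both hands.", class = "effortsens_domain_error")
  }
  if (phq9 < 0 || phq9 > 27) {
    abort("`phq9` must lie in [0, 27].", class = "effortsens_domain_error")
  }
  if (aes < 18 || aes > 72) {
    abort("`aes` must lie in [18, 72].", class = "effortsens_domain_error")
  }
  if (rating_intercept < 0 || rating_intercept > 100) {
    abort("`rating_intercept` must lie within the rating scale.",
          class = "effortsens_domain_error")
  }
  if (motor_noise_scale < 0 || rating_noise_sd < 0) {
    abort("Noise parameters must be nonnegative.", class = "effortsens_domain_error")
  }
  structure(
    list(
      id = id, age = age, sex = as.integer(sex), dominant_hand = dominant_hand,
      mvc_dom = mvc_dom, mvc_nondom = mvc_nondom,
      latent_symptom = latent_symptom, phq9 = as.integer(phq9),
      aes = as.integer(aes),
      rating_intercept = rating_intercept,
      force_sensitivity_true = force_sensitivity_true,
      failure_sensitivity_true = failure_sensitivity_true,
      motor_noise_scale = motor_noise_scale,
      rating_noise_sd = rating_noise_sd
    ),
    class = "participant_profile"
  )
}

#' Generate one trial's effort rating
#'
#' The generative rating model is quadratic in the experienced force with an
#' additive failure effect:
#' `rating = intercept + force_sensitivity * f^2 + failure_sensitivity * outcome
#'  + extra + noise`, clipped to the rating scale. `extra` carries optional
#' trial-feature contributions (e.g. overshoot, accumulated force) used by
#' [generate_cohort()].
#'
#' @param profile A [participant_profile()].
#' @param target_force_frac Experienced target force as fraction of MVC.
#' @param outcome 1 = failure, 0 = success.
#' @param seed Optional integer seed.
#' @param extra Additional deterministic rating contribution (default 0).
#' @param rating_scale Length-2 bounds for clipping.
#' @return A single rating within the scale.
#' @examples
#' p <- participant_profile(rating_intercept = 10, force_sensitivity_true = 60,
#'                          failure_sensitivity_true = 5, rating_noise_sd = 0)
#' generate_rating(p, 0.5, outcome = 0)  # 10 + 60 * 0.25 = 25
#' @export
generate_rating <- function(profile, target_force_frac, outcome, seed = NULL,
                            extra = 0, rating_scale = c(0, 100)) {
  if (!outcome %in% c(0, 1)) {
    abort("`outcome` must be 0 (success) or 1 (failure).",
          class = "effortsens_domain_error")
  }
  draw <- function() {
    mu <- profile$rating_intercept +
      profile$force_sensitivity_true * target_force_frac^2 +
      profile$failure_sensitivity_true * outcome + extra
    r <- mu + rnorm(1, 0, profile$rating_noise_sd)
    min(max(r, rating_scale[1]), rating_scale[2])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Cohort coupling specification
#'
#' Standardised (correlation-scale) couplings between the latent symptom
#' severity and the participant-level generative parameters. A coupling `c`
#' means the parameter is built as `mu + sd * (c * latent + sqrt(1 - c^2) * e)`
#' with independent standard-normal `e`, so `c` is the population correlation
#' between the parameter and the latent symptom.
#'
#' The defaults encode the study conditions the analysis is meant to recover:
#' a negative force-sensitivity coupling, a positive failure-sensitivity
#' coupling, and a moderate positive intercept coupling (higher symptom load
#' anchors ratings higher).
#'
#' @param force_slope_vs_symptom Coupling for force sensitivity, in \[-1, 1\].
#' @param failure_slope_vs_symptom Coupling for failure sensitivity.
#' @param intercept_vs_symptom Coupling for the rating intercept.
#' @return A named list.
#' @export
cohort_coupling <- function(force_slope_vs_symptom = -0.5,
                            failure_slope_vs_symptom = 0.5,
                            intercept_vs_symptom = 0.3) {
  vals <- c(force_slope_vs_symptom, failure_slope_vs_symptom, intercept_vs_symptom)
  if (any(!is.finite(vals)) || any(abs(vals) > 1)) {
    abort("Couplings must be finite correlations in [-1, 1].",
          class = "effortsens_config_error")
  }
  list(
    force_slope_vs_symptom = force_slope_vs_symptom,
    failure_slope_vs_symptom = failure_slope_vs_symptom,
    intercept_vs_symptom = intercept_vs_symptom
  )
}

#' Cohort population parameters
#'
#' Population-level means and spreads for the simulated cohort. Defaults are
#' chosen to mimic a young healthy adult sample: intercepts near 10 rating
#' units, force sensitivities near 70 (so a maximal squeeze maps to ratings
#' near the top of the scale), modest failure effects, grip MVCs of a few
#' hundred newtons with the dominant hand a little stronger, and questionnaire
#' scores centred near typical community means.
#'
#' @param intercept_mean,intercept_sd Rating intercept distribution.
#' @param force_sens_mean,force_sens_sd Force-sensitivity distribution.
#' @param failure_sens_mean,failure_sens_sd Failure-sensitivity distribution.
#' @param rating_noise_sd Trial-level rating noise SD (rating units).
#' @param motor_noise_sdlog Log-scale SD of the participant motor-noise
#'   multiplier (lognormal with median 1).
#' @param mvc_mean,mvc_sd Dominant-hand MVC distribution (newtons).
#' @param mvc_ratio_meanlog,mvc_ratio_sdlog Lognormal parameters of the
#'   dominant/nondominant MVC ratio.
#' @param aes_shared Correlation between the apathy scale's latent input and
#'   the depressive latent symptom.
#' @return A named list.
#' @export
cohort_population <- function(intercept_mean = 10, intercept_sd = 5,
                              force_sens_mean = 70, force_sens_sd = 15,
                              failure_sens_mean = 8, failure_sens_sd = 6,
                              rating_noise_sd = 7,
                              motor_noise_sdlog = 0.25,
                              mvc_mean = 350, mvc_sd = 70,
                              mvc_ratio_meanlog = log(1.07),
                              mvc_ratio_sdlog = 0.10,
                              aes_shared = 0.4) {
  as.list(environment())
}

#' Generate a synthetic cohort
#'
#' Simulates a full cohort of the force-matching effort task: per-participant
#' profiles (covariates, MVCs, symptom scores, generative sensitivities
#' coupled to a latent symptom severity), pseudo-random trial schedules with
#' strict hand alternation, force traces with signal-dependent motor noise,
#' band-hold outcomes, and quadratic-in-force effort ratings.
#'
#' Sensitivities are linear in the latent symptom with the standardised
#' couplings in `coupling`; the depressive score (PHQ9) is a bounded,
#' discretised monotone (logistic) map of the same latent, and the apathy
#' score (AES) of a partially shared latent, so symptom--sensitivity
#' associations propagate to the questionnaires.
#'
#' With `miscalibrate = TRUE` the generator emulates the cross-hand MVC
#' scaling error: the force each participant actually experiences (and that
#' drives the trace, outcome, and rating) is the nominal schedule fraction
#' applied to the *opposite* hand's MVC, i.e.
#' `experienced = nominal * MVC_opposite / MVC_own`, while the logged
#' `target_force_frac` keeps the nominal value. [correct_target_forces()]
#' recovers the experienced fractions from such a log.
#'
#' Optional `feature_effects` add trial-feature contributions to the rating
#' (computed from the simulated trace before the rating is drawn), e.g. to
#' build cohorts where initial overshoot lowers ratings and accumulated force
#' raises them.
#'
#' @param n_participants Number of participants (>= 2).
#' @param design A [task_design()].
#' @param coupling A [cohort_coupling()].
#' @param population A [cohort_population()].
#' @param feature_effects Optional named list with any of
#'   `initial_force_difference`, `cumulative_force`, `excess_force`,
#'   `coefficient_of_variation`: rating units per feature unit.
#' @param miscalibrate If `TRUE`, emulate the cross-hand MVC scaling error
#'   (see Details).
#' @param seed Integer seed; the full cohort is a pure function of the
#'   arguments and the seed.
#' @param outcome_mode Passed to [determine_outcome()].
#' @return An object of class `effort_cohort`: a list with `participants`
#'   (one row per participant; generative parameters in `sim_*` columns),
#'   `trials` (one row per trial with a `trace` list-column), and `design`.
#' @examples
#' coh <- generate_cohort(4, design = task_design(sample_rate_hz = 50), seed = 1)
#' coh
#' @export
generate_cohort <- function(n_participants,
                            design = task_design(),
                            coupling = cohort_coupling(),
                            population = cohort_population(),
                            feature_effects = NULL,
                            miscalibrate = FALSE,
                            seed = NULL,
                            outcome_mode = c("cumulative", "consecutive")) {
  if (n_participants < 2) {
    abort("`n_participants` must be at least 2.", class = "effortsens_config_error")
  }
  validate_task_design(design)
  outcome_mode <- match.arg(outcome_mode)
  pop <- population
  fe <- modifyList(
    list(initial_force_difference = 0, cumulative_force = 0,
         excess_force = 0, coefficient_of_variation = 0),
    feature_effects %||% list()
  )
  use_features <- any(unlist(fe) != 0)

  build <- function() {
    ids <- sprintf("P%03d", seq_len(n_participants))
    latent <- rnorm(n_participants)
    mix <- function(c_) c_ * latent + sqrt(1 - c_^2) * rnorm(n_participants)
    force_sens <- pop$force_sens_mean +
      pop$force_sens_sd * mix(coupling$force_slope_vs_symptom)
    fail_sens <- pop$failure_sens_mean +
      pop$failure_sens_sd * mix(coupling$failure_slope_vs_symptom)
    intercept <- pmin(pmax(
      pop$intercept_mean + pop$intercept_sd * mix(coupling$intercept_vs_symptom),
      0), 100)
    phq9 <- pmin(pmax(round(27 * stats::plogis(-1.25 + 0.75 * latent)), 0), 27)
    aes_latent <- pop$aes_shared * latent +
      sqrt(1 - pop$aes_shared^2) * rnorm(n_participants)
    aes <- pmin(pmax(18 + round(54 * stats::plogis(-1.05 + 0.55 * aes_latent)), 18), 72)
    mvc_dom <- pmax(rnorm(n_participants, pop$mvc_mean, pop$mvc_sd), 100)
    ratio <- exp(rnorm(n_participants, pop$mvc_ratio_meanlog, pop$mvc_ratio_sdlog))
    mvc_nondom <- mvc_dom / ratio
    motor_noise <- exp(rnorm(n_participants, 0, pop$motor_noise_sdlog))
    age <- pmin(pmax(round(rnorm(n_participants, 27.7, 5.8)), 18), 45)
    sex <- stats::rbinom(n_participants, 1, 0.57)
    dom_hand <- ifelse(runif(n_participants) < 0.9, "right", "left")

    participants <- tibble::tibble(
      id = ids, age = age, sex = sex, dominant_hand = dom_hand,
      mvc_dom = mvc_dom, mvc_nondom = mvc_nondom,
      phq9 = as.integer(phq9), aes = as.integer(aes),
      sim_latent_symptom = latent,
      sim_rating_intercept = intercept,
      sim_force_sensitivity = force_sens,
      sim_failure_sensitivity = fail_sens,
      sim_motor_noise_scale = motor_noise,
      sim_rating_noise_sd = pop$rating_noise_sd
    )

    trial_tabs <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      prof <- participant_profile(
        id = ids[i], age = age[i], sex = sex[i], dominant_hand = dom_hand[i],
        mvc_dom = mvc_dom[i], mvc_nondom = mvc_nondom[i],
        latent_symptom = latent[i], phq9 = phq9[i], aes = aes[i],
        rating_intercept = intercept[i],
        force_sensitivity_true = force_sens[i],
        failure_sensitivity_true = fail_sens[i],
        motor_noise_scale = motor_noise[i],
        rating_noise_sd = pop$rating_noise_sd
      )
      first_hand <- if (runif(1) < 0.5) "dominant" else "nondominant"
      sched <- generate_trial_schedule(design, first_hand)
      nt <- nrow(sched)
      # fraction of own MVC the participant actually experiences
      mis_fac <- if (miscalibrate) {
        ifelse(sched$hand == "dominant",
               mvc_nondom[i] / mvc_dom[i],
               mvc_dom[i] / mvc_nondom[i])
      } else {
        rep(1, nt)
      }
      experienced <- sched$target_force_frac * mis_fac
      traces <- vector("list", nt)
      outcome <- integer(nt)
      tib <- numeric(nt)
      rating <- numeric(nt)
      cum_auc <- 0
      for (j in seq_len(nt)) {
        f_exp <- experienced[j]
        tr <- simulate_force_trace(prof, f_exp, design, hand = sched$hand[j])
        band <- target_band(f_exp, design)
        sc <- determine_outcome(tr, band["lo"], band["hi"],
                                required_hold_s = design$required_hold_s,
                                trial_window_s = design$trial_window_s,
                                mode = outcome_mode)
        extra <- 0
        if (use_features) {
          auc <- area_under_curve(tr)
          cum_auc <- cum_auc + auc
          pk <- detect_initial_peak(tr)
          extra <- fe$initial_force_difference * (pk$peak - f_exp) +
            fe$cumulative_force * cum_auc +
            fe$excess_force * (auc - f_exp * design$required_hold_s) +
            fe$coefficient_of_variation * coefficient_of_variation(tr)
        }
        traces[[j]] <- tr
        outcome[j] <- sc$outcome
        tib[j] <- sc$time_in_band_s
        rating[j] <- generate_rating(prof, f_exp, sc$outcome, extra = extra,
                                     rating_scale = design$rating_scale)
      }
      trial_tabs[[i]] <- tibble::tibble(
        participant_id = ids[i],
        sched,
        outcome = outcome, time_in_band_s = tib, rating = rating,
        trace = traces
      )
    }
    cohort <- structure(
      list(participants = participants,
           trials = dplyr::bind_rows(trial_tabs),
           design = design),
      class = "effort_cohort"
    )
    attr(cohort, "miscalibrated") <- miscalibrate
    cohort
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.effort_cohort <- function(x, ...) {
  cat(sprintf("<effort_cohort> %d participants, %d trials\n",
              nrow(x$participants), nrow(x$trials)))
  cat(sprintf("  mean failure proportion: %.2f\n", mean(x$trials$outcome)))
  if (isTRUE(attr(x, "miscalibrated"))) {
    cat("  logged target forces carry the cross-hand MVC miscalibration\n")
  }
  invisible(x)
}

#' Re-express target fractions as the miscalibrating program logged them
#'
#' Under the cross-hand scaling error, a trial on hand *h* whose participant
#' experienced the fraction `f` of their own MVC was logged with the nominal
#' fraction `f * MVC_own / MVC_opposite` (the buggy program computed the
#' physical target as `nominal * MVC_opposite`). This operation applies that
#' relabelling to `target_force_frac`, `band_lo`, and `band_hi` -- dominant
#' trials are multiplied by `mvc_dom / mvc_nondom`, nondominant trials by
#' `mvc_nondom / mvc_dom` -- and is the exact inverse of
#' [correct_target_forces()]. Traces, outcomes, and ratings are untouched:
#' the error corrupted the logged target values, not the behaviour.
#'
#' @param cohort An `effort_cohort` whose `target_force_frac` holds
#'   experienced fractions.
#' @return The cohort with nominal (miscalibrated-log) target fractions.
#' @export
apply_miscalibration <- function(cohort) {
  stopifnot(inherits(cohort, "effort_cohort"))
  ratio <- setNames(cohort$participants$mvc_dom / cohort$participants$mvc_nondom,
                    cohort$participants$id)
  r <- ratio[cohort$trials$participant_id]
  fac <- ifelse(cohort$trials$hand == "dominant", r, 1 / r)
  cohort$trials <- dplyr::mutate(
    cohort$trials,
    target_force_frac = .data$target_force_frac * fac,
    band_lo = .data$band_lo * fac,
    band_hi = .data$band_hi * fac
  )
  attr(cohort, "miscalibrated") <- TRUE
  cohort
}
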