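#' Area under the force curve
#'
#' Trapezoidal integral of the force trace over the trial window, in
#' fraction-of-MVC seconds. Used directly as a feature (via
#' [cumulative_force()] and [excess_force()]) and as the "actual force
#' exerted" proxy in sensitivity analyses.
#'
#' @param trace A [force_trace()].
#' @return Nonnegative scalar, force x time.
#' @examples
#' area_under_curve(force_trace(rep(0.5, 1001), 250))  # 0.5 * 4 s = 2
#' @export
area_under_curve <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$samples
  if (length(x) < 2) {
    abort("Need at least two samples to integrate a trace.",
          class = "effortsens_domain_error")
  }
  pracma::trapz((seq_along(x) - 1) / trace$sample_rate_hz, x)
}

#' Coefficient of variation of a force trace
#'
#' Sample standard deviation (n - 1 denominator) of the force samples divided
#' by their mean: a dimensionless index of within-trial force instability.
#'
#' @param trace A [force_trace()].
#' @return Nonnegative scalar; `NA` (with a warning) when the mean force is 0.
#' @export
coefficient_of_variation <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  m <- mean(trace$samples)
  if (m == 0) {
    warn("Coefficient of variation undefined (mean force is 0); returning NA.")
    return(NA_real_)
  }
  sd(trace$samples) / m
}

#' Detect the initial force peak
#'
#' Scans the trace for the first strict local maximum (a sample greater than
#' both neighbours) whose height is at least `min_height` (in
#' fraction-of-MVC units). When no interior local maximum qualifies -- e.g.
#' on a monotone trace -- the global maximum is returned and the trial is
#' flagged so that every trial still yields a feature row.
#'
#' @param trace A [force_trace()].
#' @param min_height Minimal qualifying peak height (default 0.1).
#' @return A list with `peak` (force at the detected peak), `index` (sample
#'   index), and `fallback` (`TRUE` when the global-maximum fallback fired).
#' @examples
#' tr <- force_trace(c(0, 0.5, 0.3, 0.6, 0.2), 10)
#' detect_initial_peak(tr)$peak  # 0.5, the first local maximum
#' @export
detect_initial_peak <- function(trace, min_height = 0.1) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$samples
  n <- length(x)
  if (n >= 3) {
    interior <- 2:(n - 1)
    is_peak <- x[interior] > x[interior - 1] & x[interior] > x[interior + 1] &
      x[interior] >= min_height
    if (any(is_peak)) {
      idx <- interior[which(is_peak)[1]]
      return(list(peak = x[idx], index = idx, fallback = FALSE))
    }
  }
  idx <- which.max(x)
  list(peak = x[idx], index = idx, fallback = TRUE)
}

#' Initial force difference (overshoot)
#'
#' Force at the first detected peak minus the target force; positive values
#' mean the participant initially overshot the target.
#'
#' @param trace A [force_trace()].
#' @param target_force_frac Target force, fraction of MVC.
#' @param min_height Passed to [detect_initial_peak()].
#' @return Signed scalar in fraction-of-MVC units.
#' @export
initial_force_difference <- function(trace, target_force_frac, min_height = 0.1) {
  detect_initial_peak(trace, min_height)$peak - target_force_frac
}

#' Excess force
#'
#' Actual area under the force curve minus the ideal area required for
#' success (target force times the required hold duration). Negative values
#' mean less total force was produced than a just-successful hold requires.
#'
#' @param trace A [force_trace()].
#' @param target_force_frac Target force, fraction of MVC.
#' @param required_hold_s Required hold duration in seconds (default 3).
#' @return Signed scalar, force x time.
#' @export
excess_force <- function(trace, target_force_frac, required_hold_s = 3) {
  area_under_curve(trace) - target_force_frac * required_hold_s
}

#' Cumulative force up to a trial
#'
#' Sum of per-trial areas under the force curve over trials `1..up_to_index`
#' inclusive (ordered by `trial_index`): an index of accumulated motor
#' output, hence fatigue.
#'
#' @param trials One participant's trial table with a `trace` list-column,
#'   ordered by `trial_index`.
#' @param up_to_index Position (1-based, inclusive) up to which to accumulate.
#' @return Nonnegative scalar, force x time.
#' @export
cumulative_force <- function(trials, up_to_index) {
  if (up_to_index < 1 || up_to_index > nrow(trials)) {
    abort("`up_to_index` out of range.", class = "effortsens_domain_error")
  }
  trials <- dplyr::arrange(trials, .data$trial_index)
  sum(vapply(trials$trace[seq_len(up_to_index)], area_under_curve, numeric(1)))
}

#' Build the per-trial feature matrix for one participant
#'
#' Assembles the trial-level and within-trial features used to model
#' trial-by-trial effort ratings: target force (and its square), failure
#' indicator, previous trial's rating and target (perseveration and relative
#' expectation), cumulative force (fatigue), coefficient of variation (force
#' instability), initial force difference (anticipatory overshoot), excess
#' force, and the hand covariate (0 = dominant, 1 = nondominant). The first
#' trial, whose lag features are undefined, is dropped rather than imputed.
#'
#' @param trials One participant's trial table (corrected forces, ordered by
#'   `trial_index`) with a `trace` list-column.
#' @param required_hold_s Hold duration used for the excess-force ideal area.
#' @param min_height Peak threshold for [detect_initial_peak()].
#' @return A tibble with one row per trial after the first; columns
#'   `participant_id`, `trial_index`, `rating`, the features above, and
#'   bookkeeping flags `cv_defined`, `peak_fallback`.
#' @export
build_feature_matrix <- function(trials, required_hold_s = 3, min_height = 0.1) {
  if (!"trace" %in% names(trials)) {
    abort("`trials` must carry a `trace` list-column.",
          class = "effortsens_domain_error")
  }
  trials <- dplyr::arrange(trials, .data$trial_index)
  bad <- vapply(trials$trace, function(tr) !inherits(tr, "force_trace"), logical(1))
  if (any(bad)) {
    abort(paste0("Missing or invalid trace for trial index ",
                 paste(trials$trial_index[bad], collapse = ", ")),
          class = "effortsens_domain_error")
  }
  auc <- vapply(trials$trace, area_under_curve, numeric(1))
  cv <- suppressWarnings(
    vapply(trials$trace, coefficient_of_variation, numeric(1))
  )
  peaks <- lapply(trials$trace, detect_initial_peak, min_height = min_height)
  peak_force <- vapply(peaks, `[[`, numeric(1), "peak")
  peak_fb <- vapply(peaks, `[[`, logical(1), "fallback")

  out <- tibble::tibble(
    participant_id = trials$participant_id,
    trial_index = trials$trial_index,
    rating = trials$rating,
    target_force = trials$target_force_frac,
    target_force_sq = trials$target_force_frac^2,
    failure = trials$outcome,
    rating_lag1 = dplyr::lag(trials$rating),
    target_lag1 = dplyr::lag(trials$target_force_frac),
    cumulative_force = cumsum(auc),
    coefficient_of_variation = cv,
    initial_force_difference = peak_force - trials$target_force_frac,
    excess_force = auc - trials$target_force_frac * required_hold_s,
    auc = auc,
    hand = as.integer(trials$hand == "nondominant"),
    cv_defined = !is.na(cv),
    peak_fallback = peak_fb
  )
  out[-1, , drop = FALSE]
}

#' Build feature matrices for a whole cohort
#'
#' @param cohort An `effort_cohort` (typically the retained cohort from
#'   [preprocess_cohort()]).
#' @inheritParams build_feature_matrix
#' @return A tibble stacking every participant's feature rows.
#' @export
build_cohort_features <- function(cohort, required_hold_s = NULL,
                                  min_height = 0.1) {
  hold <- required_hold_s %||% cohort$design$required_hold_s %||% 3
  cohort$trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map(build_feature_matrix, required_hold_s = hold,
               min_height = min_height) |>
    dplyr::bind_rows()
}

#' Canonical feature column names used in the ridge analysis
#' @return Character vector of feature column names.
#' @export
feature_columns <- function() {
  c("target_force", "failure", "rating_lag1", "target_lag1",
    "cumulative_force", "coefficient_of_variation",
    "initial_force_difference", "excess_force", "hand")
}
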