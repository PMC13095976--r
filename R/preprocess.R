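#' Correct target forces for the cross-hand MVC scaling error
#'
#' Recomputes the force fraction each participant actually experienced from
#' the logged nominal fraction: dominant-hand targets are multiplied by
#' `mvc_nondom / mvc_dom` and nondominant-hand targets by
#' `mvc_dom / mvc_nondom` (the buggy acquisition program scaled each trial's
#' physical target by the opposite hand's MVC). Band bounds are rescaled with
#' the target; all other columns are untouched.
#'
#' @param trials Trial table with `participant_id`, `hand`,
#'   `target_force_frac`, `band_lo`, `band_hi`.
#' @param participants Participant table with `id`, `mvc_dom`, `mvc_nondom`.
#' @return The trial table with corrected force columns.
#' @examples
#' p <- tibble::tibble(id = "P1", mvc_dom = 400, mvc_nondom = 300)
#' tr <- tibble::tibble(participant_id = "P1", hand = "dominant",
#'                      target_force_frac = 0.4, band_lo = 0.38, band_hi = 0.42)
#' correct_target_forces(tr, p)$target_force_frac  # 0.3
#' @export
correct_target_forces <- function(trials, participants) {
  if (inherits(trials, "effort_cohort")) {
    trials$trials <- correct_target_forces(trials$trials, trials$participants)
    attr(trials, "miscalibrated") <- FALSE
    return(trials)
  }
  if (any(!is.finite(participants$mvc_dom)) || any(participants$mvc_dom <= 0) ||
      any(!is.finite(participants$mvc_nondom)) || any(participants$mvc_nondom <= 0)) {
    abort("All MVC values must be positive and finite.",
          class = "effortsens_domain_error")
  }
  missing_ids <- setdiff(unique(trials$participant_id), participants$id)
  if (length(missing_ids) > 0) {
    abort(paste0("No MVC record for participant(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "effortsens_domain_error")
  }
  ratio <- setNames(participants$mvc_dom / participants$mvc_nondom,
                    participants$id)
  r <- ratio[trials$participant_id]
  fac <- ifelse(trials$hand == "dominant", 1 / r, r)
  dplyr::mutate(
    trials,
    target_force_frac = .data$target_force_frac * fac,
    band_lo = .data$band_lo * fac,
    band_hi = .data$band_hi * fac
  )
}

#' MVC ratio (dominant over nondominant)
#'
#' @param participants Participant table with `mvc_dom`, `mvc_nondom` (> 0).
#' @return The table with an `mvc_ratio` column appended.
#' @export
compute_mvc_ratio <- function(participants) {
  if (any(!is.finite(participants$mvc_nondom)) || any(participants$mvc_nondom <= 0) ||
      any(!is.finite(participants$mvc_dom)) || any(participants$mvc_dom <= 0)) {
    abort("MVC values must be positive to form a ratio.",
          class = "effortsens_domain_error")
  }
  dplyr::mutate(participants, mvc_ratio = .data$mvc_dom / .data$mvc_nondom)
}

#' Exclude the top quartile of MVC ratios
#'
#' Removes the `floor(n / 4)` participants with the largest dominant/
#' nondominant MVC ratios (exactly n/4 when n is divisible by 4, so a
#' 108-participant cohort retains 81). Ties at the boundary are broken by
#' stable participant-id order and noted in the report.
#'
#' @param participants Participant table; `mvc_ratio` is computed if absent.
#' @return A list with `retained` (participant table), `excluded` (ids), and
#'   `report` (per-participant ratio and flag).
#' @export
exclude_top_quartile_ratio <- function(participants) {
  if (nrow(participants) < 4) {
    abort("Quartile exclusion needs at least 4 participants.",
          class = "effortsens_domain_error")
  }
  if (!"mvc_ratio" %in% names(participants)) {
    participants <- compute_mvc_ratio(participants)
  }
  n_remove <- floor(nrow(participants) / 4)
  ord <- order(-participants$mvc_ratio, participants$id)
  excluded_ids <- participants$id[ord[seq_len(n_remove)]]
  boundary <- participants$mvc_ratio[ord[n_remove]]
  tie_broken <- n_remove < nrow(participants) &&
    isTRUE(all.equal(boundary, participants$mvc_ratio[ord[n_remove + 1]]))
  report <- tibble::tibble(
    id = participants$id,
    mvc_ratio = participants$mvc_ratio,
    quartile_excluded = participants$id %in% excluded_ids
  )
  list(
    retained = dplyr::filter(participants, !.data$id %in% excluded_ids),
    excluded = excluded_ids,
    report = report,
    n_removed = n_remove,
    tie_at_boundary = tie_broken
  )
}

#' Per-participant Spearman correlation between force and rating
#'
#' Rank correlation (average ranks for ties) between the corrected target
#' force and the effort rating across a participant's trials. Participants
#' engaging with the task are expected to show a strongly positive value.
#'
#' @param trials Trial table with `participant_id`, `target_force_frac`,
#'   `rating`.
#' @return A tibble with `participant_id`, `spearman_rho` (NA when either
#'   variable has zero variance), and `rho_defined`.
#' @export
spearman_force_rating <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      spearman_rho = if (dplyr::n() < 3 ||
                         sd(.data$rating) == 0 ||
                         sd(.data$target_force_frac) == 0) {
        NA_real_
      } else {
        cor(.data$target_force_frac, .data$rating, method = "spearman")
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(rho_defined = !is.na(.data$spearman_rho))
}

#' Apply outlier-based participant exclusions
#'
#' On a cohort snapshot (normally the post-quartile cohort), computes each
#' participant's Spearman force--rating correlation and failure proportion,
#' then excludes participants outside `mean +/- sd_threshold * SD` on either
#' statistic, participants with an undefined correlation, and participants
#' who succeeded on every trial (an all-success participant makes the failure
#' predictor constant, so the first-level regression would be rank
#' deficient). Statistics for both criteria are computed on the same
#' snapshot, not sequentially re-estimated.
#'
#' @param trials Trial table (corrected forces).
#' @param participants Participant table for the same snapshot.
#' @param sd_threshold Outlier threshold in SD units (default 2.5).
#' @return A list with `retained` participants, `report` (per-participant
#'   statistics and flags), and `thresholds`.
#' @export
apply_outlier_exclusions <- function(trials, participants, sd_threshold = 2.5) {
  trials <- dplyr::filter(trials, .data$participant_id %in% participants$id)
  rho <- spearman_force_rating(trials)
  fp <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(failure_proportion = mean(.data$outcome), .groups = "drop")
  stats_tab <- dplyr::left_join(rho, fp, by = "participant_id")

  band <- function(x) {
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) c(-Inf, Inf, m, s) else c(m - sd_threshold * s, m + sd_threshold * s, m, s)
  }
  rb <- band(stats_tab$spearman_rho)
  fb <- band(stats_tab$failure_proportion)

  report <- stats_tab |>
    dplyr::mutate(
      spearman_outlier = !is.na(.data$spearman_rho) &
        (.data$spearman_rho < rb[1] | .data$spearman_rho > rb[2]),
      spearman_undefined = !.data$rho_defined,
      failure_outlier = .data$failure_proportion < fb[1] |
        .data$failure_proportion > fb[2],
      all_success = .data$failure_proportion == 0,
      excluded = .data$spearman_outlier | .data$spearman_undefined |
        .data$failure_outlier | .data$all_success
    )
  retained_ids <- report$participant_id[!report$excluded]
  list(
    retained = dplyr::filter(participants, .data$id %in% retained_ids),
    report = report,
    thresholds = list(
      sd_threshold = sd_threshold,
      spearman_mean = rb[3], spearman_sd = rb[4],
      failure_mean = fb[3], failure_sd = fb[4],
      spearman_sd_degenerate = rb[4] == 0,
      failure_sd_degenerate = fb[4] == 0
    )
  )
}

#' Preprocess a cohort: correction, quartile exclusion, outlier exclusion
#'
#' Runs the full preprocessing chain: (1) correct the logged target forces for
#' the cross-hand MVC scaling error, (2) compute MVC ratios and drop the top
#' quartile (participants for whom the two hands' targets were most
#' mismatched), (3) apply the outlier and all-success exclusions on the
#' retained snapshot. Returns the retained cohort and an auditable exclusion
#' report whose counts reconcile at every step.
#'
#' @param cohort An `effort_cohort` (or a list with `trials`, `participants`,
#'   `design`).
#' @param sd_threshold Outlier threshold in SD units (default 2.5).
#' @param correct Whether to apply [correct_target_forces()] first. The
#'   default (`NULL`) corrects unless the cohort carries a `miscalibrated`
#'   attribute set to `FALSE` (i.e. simulated cohorts known to log experienced
#'   fractions are left alone; real or miscalibrated logs are corrected).
#' @return A list of class `effort_preprocessed`: `cohort` (retained trials +
#'   participants), `exclusions` (per-participant report), `counts`
#'   (participants retained at each step), `thresholds`.
#' @export
preprocess_cohort <- function(cohort, sd_threshold = 2.5, correct = NULL) {
  trials <- cohort$trials
  participants <- compute_mvc_ratio(cohort$participants)
  if (is.null(correct)) {
    mis <- attr(cohort, "miscalibrated")
    correct <- is.null(mis) || isTRUE(mis)
  }
  if (correct) trials <- correct_target_forces(trials, participants)

  n0 <- nrow(participants)
  q <- exclude_top_quartile_ratio(participants)
  n1 <- nrow(q$retained)
  trials_q <- dplyr::filter(trials, .data$participant_id %in% q$retained$id)
  o <- apply_outlier_exclusions(trials_q, q$retained, sd_threshold = sd_threshold)
  n2 <- nrow(o$retained)

  exclusions <- q$report |>
    dplyr::left_join(dplyr::rename(o$report, id = "participant_id"), by = "id") |>
    dplyr::mutate(dplyr::across(
      c("spearman_outlier", "spearman_undefined", "failure_outlier",
        "all_success"),
      ~ dplyr::coalesce(.x, FALSE)
    )) |>
    dplyr::mutate(excluded = .data$quartile_excluded | dplyr::coalesce(.data$excluded, FALSE))

  retained_trials <- dplyr::filter(trials, .data$participant_id %in% o$retained$id)
  out <- list(
    cohort = structure(
      list(participants = o$retained, trials = retained_trials,
           design = cohort$design),
      class = "effort_cohort"
    ),
    exclusions = exclusions,
    counts = c(input = n0, after_quartile = n1, after_outliers = n2),
    thresholds = o$thresholds
  )
  class(out) <- "effort_preprocessed"
  out
}

#' @export
print.effort_preprocessed <- function(x, ...) {
  cat("<effort_preprocessed>\n")
  cat(sprintf("  participants: %d -> %d (quartile) -> %d (outliers/all-success)\n",
              x$counts["input"], x$counts["after_quartile"],
              x$counts["after_outliers"]))
  invisible(x)
}
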