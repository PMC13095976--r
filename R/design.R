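#' Task design for the force-matching effort task
#'
#' Describes one session of the grip force-matching task: on every trial the
#' participant squeezes a hand dynamometer so that the exerted force stays
#' inside a band around a target level (expressed as a fraction of that hand's
#' maximal voluntary contraction, MVC), holding it there for a required total
#' time within a fixed trial window. Hands alternate on consecutive trials.
#' After each trial the participant rates perceived effort on a bounded
#' visual-analogue scale.
#'
#' The defaults encode the standard session: five target levels
#' (20--100% MVC), four repetitions per level and hand except three at the
#' maximal level (to limit fatigue), a +/- 5% multiplicative target band, a
#' 7-s trial window with a 3-s required hold, a 0--100 rating scale, and
#' 250 Hz force sampling. That yields 2 x (4 x 4 + 3) = 38 trials.
#'
#' @param force_levels Target forces as fractions of MVC, strictly increasing.
#' @param reps_per_level Repetitions per hand for every level except the
#'   highest.
#' @param reps_max_level Repetitions per hand at the highest level.
#' @param band_halfwidth_rel Relative half-width of the target band; the band
#'   is `target * (1 - band_halfwidth_rel)` to `target * (1 + band_halfwidth_rel)`.
#' @param trial_window_s Trial window length in seconds.
#' @param required_hold_s Total in-band time (seconds) required for success;
#'   must be smaller than `trial_window_s`.
#' @param rating_scale Length-2 numeric, bounds of the effort rating scale.
#' @param sample_rate_hz Force sampling rate in Hz.
#' @param break_s Inter-trial break in seconds (metadata only; no simulated
#'   process depends on it).
#'
#' @return An object of class `task_design` (a validated list).
#' @examples
#' d <- task_design()
#' n_trials(d)
#' @export
task_design <- function(force_levels = c(0.20, 0.40, 0.60, 0.80, 1.00),
                        reps_per_level = 4L,
                        reps_max_level = 3L,
                        band_halfwidth_rel = 0.05,
                        trial_window_s = 7,
                        required_hold_s = 3,
                        rating_scale = c(0, 100),
                        sample_rate_hz = 250,
                        break_s = 20) {
  design <- structure(
    list(
      force_levels = sort(as.numeric(force_levels)),
      reps_per_level = as.integer(reps_per_level),
      reps_max_level = as.integer(reps_max_level),
      band_halfwidth_rel = band_halfwidth_rel,
      trial_window_s = trial_window_s,
      required_hold_s = required_hold_s,
      rating_scale = as.numeric(rating_scale),
      sample_rate_hz = sample_rate_hz,
      break_s = break_s
    ),
    class = "task_design"
  )
  validate_task_design(design)
  design
}

validate_task_design <- function(design) {
  if (!inherits(design, "task_design")) {
    abort("`design` must be created with `task_design()`.", class = "effortsens_config_error")
  }
  with(design, {
    if (length(force_levels) < 1 || any(force_levels <= 0) || anyDuplicated(force_levels)) {
      abort("`force_levels` must be distinct positive fractions of MVC.",
            class = "effortsens_config_error")
    }
    if (reps_per_level < 1 || reps_max_level < 1) {
      abort("Repetition counts must be at least 1.", class = "effortsens_config_error")
    }
    if (band_halfwidth_rel <= 0 || band_halfwidth_rel >= 1) {
      abort("`band_halfwidth_rel` must be in (0, 1).", class = "effortsens_config_error")
    }
    if (required_hold_s >= trial_window_s) {
      abort("`required_hold_s` must be smaller than `trial_window_s`.",
            class = "effortsens_config_error")
    }
    if (length(rating_scale) != 2 || rating_scale[1] >= rating_scale[2]) {
      abort("`rating_scale` must be two increasing bounds.", class = "effortsens_config_error")
    }
    if (sample_rate_hz <= 0) {
      abort("`sample_rate_hz` must be positive.", class = "effortsens_config_error")
    }
  })
  invisible(design)
}

#' Number of trials in one session
#'
#' Both hands perform `reps_per_level` trials at every force level except the
#' highest, which gets `reps_max_level` trials per hand.
#'
#' @param design A [task_design()].
#' @return Integer trial count (38 under the default design).
#' @export
n_trials <- function(design) {
  validate_task_design(design)
  k <- length(design$force_levels)
  2L * ((k - 1L) * design$reps_per_level + design$reps_max_level)
}

#' Per-hand multiset of target forces
#' @noRd
hand_targets <- function(design) {
  k <- length(design$force_levels)
  rep(design$force_levels,
      times = c(rep(design$reps_per_level, k - 1L), design$reps_max_level))
}

#' Target band bounds for a target force
#' @noRd
target_band <- function(target_force_frac, design) {
  c(lo = target_force_frac * (1 - design$band_halfwidth_rel),
    hi = target_force_frac * (1 + design$band_halfwidth_rel))
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design>\n")
  cat("  force levels (frac MVC):", paste(format(x$force_levels), collapse = ", "), "\n")
  cat("  reps per level (hand):", x$reps_per_level, "(", x$reps_max_level, "at max level )\n")
  cat("  trials per session:", n_trials(x), "\n")
  cat("  band: +/-", x$band_halfwidth_rel * 100, "% of target\n")
  cat("  window:", x$trial_window_s, "s; required hold:", x$required_hold_s, "s\n")
  cat("  rating scale:", x$rating_scale[1], "-", x$rating_scale[2], "\n")
  cat("  sampling:", x$sample_rate_hz, "Hz\n")
  invisible(x)
}

#' Generate a pseudo-random trial schedule
#'
#' Shuffles each hand's multiset of target forces independently and interleaves
#' the two hands in strict alternation, starting with `first_hand`. This mirrors
#' the session structure in which hands alternate on every trial to limit
#' muscle fatigue while each hand sees the full set of repetitions.
#'
#' @param design A [task_design()].
#' @param first_hand `"dominant"` or `"nondominant"`; which hand performs trial 1.
#' @param seed Optional integer seed; when supplied the schedule is a pure
#'   function of (design, first_hand, seed).
#' @return A tibble with columns `trial_index`, `hand`, `target_force_frac`,
#'   `band_lo`, `band_hi`.
#' @examples
#' sched <- generate_trial_schedule(task_design(), "dominant", seed = 1)
#' nrow(sched)
#' table(sched$hand, sched$target_force_frac)
#' @export
generate_trial_schedule <- function(design = task_design(),
                                    first_hand = c("dominant", "nondominant"),
                                    seed = NULL) {
  validate_task_design(design)
  first_hand <- match.arg(first_hand)
  draw <- function() {
    targets <- hand_targets(design)
    a <- sample(targets)
    b <- sample(targets)
    # strict alternation: a = first hand, b = second hand
    tf <- as.numeric(rbind(a, b))
    hands <- rep(
      if (first_hand == "dominant") c("dominant", "nondominant")
      else c("nondominant", "dominant"),
      length(targets)
    )
    tibble::tibble(
      trial_index = seq_along(tf),
      hand = hands,
      target_force_frac = tf,
      band_lo = tf * (1 - design$band_halfwidth_rel),
      band_hi = tf * (1 + design$band_halfwidth_rel)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
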