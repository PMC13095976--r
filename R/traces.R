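#' Construct a force trace
#'
#' A force trace is one trial's uniformly sampled force time series, stored in
#' fraction-of-MVC units for the hand that performed the trial.
#'
#' @param samples Numeric vector of nonnegative force values (fraction of MVC).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param hand `"dominant"` or `"nondominant"`.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(samples, sample_rate_hz, hand = "dominant") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) {
    abort("A force trace needs at least one sample.", class = "effortsens_domain_error")
  }
  if (any(!is.finite(samples)) || any(samples < 0)) {
    abort("Force samples must be finite and nonnegative.", class = "effortsens_domain_error")
  }
  if (sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be positive.", class = "effortsens_domain_error")
  }
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz, hand = hand),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz (%.2f s), hand = %s\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$hand))
  invisible(x)
}

#' @describeIn force_trace Convert to a tibble with `time_s` and `force` columns.
#' @param x A `force_trace`.
#' @param ... Unused.
#' @method as_tibble force_trace
#' @export
as_tibble.force_trace <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$sample_rate_hz,
    force = x$samples
  )
}

#' Simulate one trial's force trace
#'
#' Generative stand-in for a recorded dynamometer trace. The trace rises
#' linearly from zero over `ramp_s` toward an intended level near the target,
#' with three stochastic components, all scaled by the participant's
#' `motor_noise_scale`:
#'
#' * an *aiming error*: the intended level is `target * (1 + e)` with
#'   `e ~ N(0, aim_coef * exp(aim_rate * target))` — force reproduction
#'   degrades steeply as the target approaches maximal contraction, which is
#'   what makes failure probability rise with target force;
#' * an *initial overshoot/undershoot*: the ramp peaks at
#'   `intended * (1 + o)`, `o ~ N(0, overshoot_sd)`, then settles
#'   exponentially (time constant `settle_tau_s`) back to the intended level;
#' * *signal-dependent wobble*: an Ornstein--Uhlenbeck process (correlation
#'   time `ou_tau_s`) whose stationary standard deviation is proportional to
#'   the intended level (`ou_coef * intended`), ramped in with the trace so
#'   the trace starts at zero.
#'
#' With `motor_noise_scale = 0` all three components vanish and the trace
#' ramps up and holds exactly at the target. Samples are truncated at the
#' trial window and clipped at zero (a dynamometer cannot record negative
#' grip force).
#'
#' @param profile A [participant_profile()] (only `motor_noise_scale` and the
#'   hand-specific metadata are used).
#' @param target_force_frac Target force as a fraction of the squeezing hand's
#'   MVC; must be positive.
#' @param design A [task_design()]; supplies window length and sampling rate.
#' @param seed Optional integer seed for a reproducible trace.
#' @param hand Hand label stored on the trace.
#' @param ramp_s Ramp duration in seconds.
#' @param settle_tau_s Settling time constant for the initial overshoot.
#' @param ou_tau_s Correlation time of the wobble process.
#' @param aim_coef,aim_rate Coefficient and exponential rate of the aiming
#'   error's relative standard deviation as a function of target force.
#' @param overshoot_sd Relative standard deviation of the initial overshoot.
#' @param ou_coef Wobble stationary standard deviation per unit intended level.
#' @return A [force_trace()].
#' @export
simulate_force_trace <- function(profile, target_force_frac,
                                 design = task_design(), seed = NULL,
                                 hand = "dominant",
                                 ramp_s = 0.6, settle_tau_s = 0.4,
                                 ou_tau_s = 0.25,
                                 aim_coef = 0.022, aim_rate = 2.5,
                                 overshoot_sd = 0.12, ou_coef = 0.04) {
  if (!is.finite(target_force_frac) || target_force_frac <= 0) {
    abort("`target_force_frac` must be positive.", class = "effortsens_domain_error")
  }
  validate_task_design(design)
  s <- profile$motor_noise_scale
  if (is.null(s) || !is.finite(s) || s < 0) {
    abort("`profile$motor_noise_scale` must be a nonnegative number.",
          class = "effortsens_domain_error")
  }
  draw <- function() {
    rate <- design$sample_rate_hz
    n <- floor(design$trial_window_s * rate)
    t <- (seq_len(n) - 1) / rate
    aim_sd <- s * aim_coef * exp(aim_rate * target_force_frac)
    aim <- max(rnorm(1, 0, aim_sd), -0.9)
    intended <- target_force_frac * (1 + aim)
    over <- max(rnorm(1, 0, s * overshoot_sd), -0.9)
    peak <- intended * (1 + over)
    # deterministic profile: linear ramp to the peak, exponential settle
    prof <- ifelse(
      t < ramp_s,
      peak * t / ramp_s,
      intended + (peak - intended) * exp(-(t - ramp_s) / settle_tau_s)
    )
    sigma <- s * ou_coef * intended
    if (sigma > 0) {
      a <- exp(-1 / (rate * ou_tau_s))
      innov <- rnorm(n, 0, sigma * sqrt(1 - a^2))
      ou <- as.numeric(stats::filter(innov, a, method = "recursive"))
      # scale the wobble with the deterministic envelope so the trace leaves 0
      prof <- prof + ou * pmin(prof / intended, 1)
    }
    force_trace(pmax(prof, 0), sample_rate_hz = rate, hand = hand)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Score a trial from its force trace
#'
#' A trial succeeds when the force stays inside the target band for at least
#' `required_hold_s` seconds within the trial window. In-band time is counted
#' as the number of samples with `band_lo <= force <= band_hi` divided by the
#' sampling rate. By default accumulation is *cumulative* (separate in-band
#' episodes add up); `mode = "consecutive"` instead requires a single
#' uninterrupted in-band run of the required length.
#'
#' @param trace A [force_trace()].
#' @param band_lo,band_hi Band bounds in the same units as the trace.
#' @param required_hold_s Required in-band time (seconds).
#' @param trial_window_s Scoring window (seconds); samples beyond it are
#'   ignored.
#' @param mode `"cumulative"` (default) or `"consecutive"`.
#' @return A list with `outcome` (1 = failure, 0 = success) and
#'   `time_in_band_s` (cumulative in-band time within the window).
#' @examples
#' tr <- force_trace(rep(0.4, 1000), 250)
#' determine_outcome(tr, 0.38, 0.42, required_hold_s = 3, trial_window_s = 7)
#' @export
determine_outcome <- function(trace, band_lo, band_hi,
                              required_hold_s = 3, trial_window_s = 7,
                              mode = c("cumulative", "consecutive")) {
  mode <- match.arg(mode)
  if (!inherits(trace, "force_trace")) {
    abort("`trace` must be a force_trace.", class = "effortsens_domain_error")
  }
  if (band_lo >= band_hi) {
    abort("`band_lo` must be below `band_hi`.", class = "effortsens_domain_error")
  }
  rate <- trace$sample_rate_hz
  n_window <- min(length(trace$samples), floor(trial_window_s * rate))
  if (n_window < 1) {
    abort("Empty trace within the scoring window.", class = "effortsens_domain_error")
  }
  x <- trace$samples[seq_len(n_window)]
  in_band <- x >= band_lo & x <= band_hi
  time_in_band <- sum(in_band) / rate
  held <- if (mode == "cumulative") {
    time_in_band >= required_hold_s
  } else {
    r <- rle(in_band)
    any(r$values & r$lengths / rate >= required_hold_s)
  }
  list(outcome = as.integer(!held), time_in_band_s = time_in_band)
}
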