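#' Mean effort rating as a function of binned target force
#'
#' For each participant, ratings are averaged within equal-width force bins;
#' bin means are then averaged across participants (error bars: SEM across
#' participants). This is the standard psychophysics view of the
#' force-to-rating curve.
#'
#' @param trials Trial table with `participant_id`, `target_force_frac`,
#'   `rating` (or `outcome` for [plot_failure_force()]).
#' @param bins Number of equal-width force bins (default 10).
#' @return A ggplot object.
#' @export
plot_rating_force <- function(trials, bins = 10) {
  binned_summary(trials, "rating", bins) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$force_mid, y = .data$grand_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$grand_mean - .data$sem,
                                          ymax = .data$grand_mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target force (fraction of MVC)",
                  y = "mean effort rating") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rating_force
#' @export
plot_failure_force <- function(trials, bins = 10) {
  binned_summary(trials, "outcome", bins) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$force_mid, y = .data$grand_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$grand_mean - .data$sem,
                                          ymax = .data$grand_mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target force (fraction of MVC)",
                  y = "failure rate") +
    ggplot2::theme_minimal()
}

binned_summary <- function(trials, var, bins) {
  rng <- range(trials$target_force_frac)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  trials |>
    dplyr::mutate(bin = pmin(findInterval(.data$target_force_frac, breaks,
                                          all.inside = TRUE), bins)) |>
    dplyr::group_by(.data$participant_id, .data$bin) |>
    dplyr::summarise(m = mean(.data[[var]]), .groups = "drop") |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      grand_mean = mean(.data$m),
      sem = sd(.data$m) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_participants > 1) |>
    dplyr::mutate(force_mid = mids[.data$bin])
}
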