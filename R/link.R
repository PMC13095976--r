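#' Transform force under a candidate link function
#'
#' Candidate parameter-free transforms of the force fraction used when
#' modelling the force-to-rating relationship: `linear` (identity),
#' `quadratic` (`f^2`), `hyperbolic` (`f / (1 + f)`), and `exponential`
#' (`exp(f) - 1`). Parameter-free forms keep the mixed model linear in its
#' coefficients.
#'
#' @param force_frac Nonnegative force fraction(s) of MVC.
#' @param link One of `"linear"`, `"quadratic"`, `"hyperbolic"`,
#'   `"exponential"`.
#' @return Transformed predictor, same length as `force_frac`.
#' @examples
#' transform_force(0.5, "quadratic")   # 0.25
#' transform_force(1.0, "hyperbolic")  # 0.5
#' @export
transform_force <- function(force_frac, link) {
  if (any(force_frac < 0, na.rm = TRUE)) {
    abort("`force_frac` must be nonnegative.", class = "effortsens_domain_error")
  }
  switch(
    link,
    linear = force_frac,
    quadratic = force_frac^2,
    hyperbolic = force_frac / (1 + force_frac),
    exponential = exp(force_frac) - 1,
    abort(paste0("Unknown link function: '", link, "'."),
          class = "effortsens_config_error")
  )
}

link_functions <- function() c("linear", "quadratic", "hyperbolic", "exponential")

#' Fit the force-to-rating link model grid
#'
#' Fits linear mixed-effects models predicting the effort rating from the
#' transformed force plus a fixed hand effect, for every combination of the
#' four link functions and two random-effects structures (by-participant
#' random intercept; random intercept + random slope on the transformed
#' force). Models are estimated by full maximum likelihood so that BIC
#' (`k * ln(N) - 2 * lnL`, `N` = number of trials) is comparable across the
#' grid. Ratings are rescaled to `[0, 1]` internally to stabilise the
#' optimiser; the same rescaling is applied to every cell, which leaves BIC
#' differences (and hence the selection) unchanged.
#'
#' @param trials Trial table with `participant_id`, `target_force_frac`,
#'   `hand`, `rating`.
#' @param rating_scale Bounds used for the internal rescaling.
#' @param rescale_ratings Logical; rescale ratings to `[0, 1]` before fitting.
#' @return An object of class `link_comparison`: a tibble grid with columns
#'   `link`, `random_effects`, `bic`, `logLik`, `n_par`, `converged`, plus
#'   attributes `selected` and `n_obs`.
#' @export
fit_link_models <- function(trials, rating_scale = c(0, 100),
                            rescale_ratings = TRUE) {
  if (length(unique(trials$participant_id)) < 2) {
    abort("Need at least 2 participants to fit mixed models.",
          class = "effortsens_domain_error")
  }
  dat <- data.frame(
    pid = trials$participant_id,
    hand = as.integer(trials$hand == "nondominant"),
    force = trials$target_force_frac,
    rating = if (rescale_ratings) {
      (trials$rating - rating_scale[1]) / diff(rating_scale)
    } else {
      trials$rating
    }
  )
  grid <- tidyr::expand_grid(
    link = link_functions(),
    random_effects = c("intercept", "intercept_slope")
  )
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit_cell <- function(link, random_effects) {
    dat$tf <- transform_force(dat$force, link)
    form <- if (random_effects == "intercept") {
      rating ~ tf + hand + (1 | pid)
    } else {
      rating ~ tf + hand + (1 + tf | pid)
    }
    fit <- tryCatch(
      suppressWarnings(
        suppressMessages(lme4::lmer(form, data = dat, REML = FALSE, control = ctrl))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(bic = NA_real_, logLik = NA_real_,
                            n_par = NA_integer_, converged = FALSE))
    }
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0 &&
      fit@optinfo$conv$opt == 0
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    tibble::tibble(
      bic = k * log(nrow(dat)) - 2 * ll,
      logLik = ll, n_par = as.integer(k), converged = conv
    )
  }
  res <- dplyr::bind_cols(
    grid,
    purrr::map2_dfr(grid$link, grid$random_effects, fit_cell)
  )
  structure(res,
            class = c("link_comparison", class(res)),
            selected = select_best(res),
            n_obs = nrow(dat))
}

#' Select the best link model by BIC
#'
#' Returns the converged grid cell with minimum BIC. Exact ties are broken
#' toward the simpler random-effects structure, then toward the link order
#' linear, quadratic, hyperbolic, exponential.
#'
#' @param comparison A `link_comparison` grid (or a compatible data frame with
#'   columns `link`, `random_effects`, `bic`, `converged`).
#' @return A list with `link` and `random_effects`.
#' @export
select_best <- function(comparison) {
  tab <- as.data.frame(comparison)[, c("link", "random_effects", "bic", "converged")]
  tab <- tab[tab$converged & is.finite(tab$bic), , drop = FALSE]
  if (nrow(tab) == 0) {
    abort("No converged link model to select from.",
          class = "effortsens_domain_error")
  }
  tab$re_rank <- match(tab$random_effects, c("intercept", "intercept_slope"))
  tab$link_rank <- match(tab$link, link_functions())
  tab <- tab[order(tab$bic, tab$re_rank, tab$link_rank), , drop = FALSE]
  list(link = tab$link[1], random_effects = tab$random_effects[1])
}

#' @export
print.link_comparison <- function(x, ...) {
  cat("<link_comparison> BIC grid (lower is better)\n")
  print(tibble::as_tibble(x))
  sel <- attr(x, "selected")
  cat(sprintf("selected: %s link, %s random effects\n",
              sel$link, sel$random_effects))
  invisible(x)
}

#' @rdname fit_link_models
#' @param x A `link_comparison`.
#' @param ... Unused.
#' @method tidy link_comparison
#' @export
tidy.link_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname fit_link_models
#' @method glance link_comparison
#' @export
glance.link_comparison <- function(x, ...) {
  sel <- attr(x, "selected")
  tab <- tibble::as_tibble(x)
  best <- tab[tab$link == sel$link & tab$random_effects == sel$random_effects, ]
  tibble::tibble(
    selected_link = sel$link,
    selected_random_effects = sel$random_effects,
    bic = best$bic, logLik = best$logLik,
    n_obs = attr(x, "n_obs"),
    n_converged = sum(tab$converged)
  )
}

#' @rdname fit_link_models
#' @param object A `link_comparison`.
#' @method autoplot link_comparison
#' @export
autoplot.link_comparison <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  sel <- attr(object, "selected")
  tab$selected <- tab$link == sel$link & tab$random_effects == sel$random_effects
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$link, y = .data$bic,
                                    fill = .data$random_effects,
                                    alpha = .data$selected)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.5),
                                guide = "none") +
    ggplot2::labs(x = "link function", y = "BIC",
                  fill = "random effects",
                  title = "Force-to-rating link selection") +
    ggplot2::theme_minimal()
}
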