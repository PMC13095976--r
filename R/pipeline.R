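#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serialisable
#' list, so a run is reproducible from the config and seed alone.
#'
#' @param n_participants Cohort size when simulating (default 108).
#' @param seed Integer seed for the whole run.
#' @param design A [task_design()] or a named list of overrides for it.
#' @param coupling A [cohort_coupling()] or override list.
#' @param population A [cohort_population()] or override list.
#' @param miscalibrate Emulate the cross-hand MVC scaling error when
#'   simulating (default `TRUE`, matching the study conditions).
#' @param input_dir Optional directory with user-supplied cohort CSVs (see
#'   [read_cohort()]); when given, no simulation happens.
#' @param sd_threshold Outlier threshold in SD units (default 2.5).
#' @param outcome_mode `"cumulative"` or `"consecutive"` hold rule.
#' @param huber_k Huber tuning constant (default 1.345).
#' @param lambda Ridge shrinkage grid.
#' @param cv_k Ridge cross-validation folds (default 10).
#' @param weighted_cv Use trial weights in validation MSE (default `TRUE`).
#' @param rating_cap Rating cap for the intercept sensitivity analysis
#'   (default 90: re-estimates intercepts without near-ceiling trials).
#' @param write_traces Write `traces.csv` (default `FALSE`; it is large).
#' @return A list of class `effort_config`.
#' @export
effort_config <- function(n_participants = 108, seed = 1,
                          design = task_design(),
                          coupling = cohort_coupling(),
                          population = cohort_population(),
                          miscalibrate = TRUE,
                          input_dir = NULL,
                          sd_threshold = 2.5,
                          outcome_mode = "cumulative",
                          huber_k = 1.345,
                          lambda = default_lambda_grid(),
                          cv_k = 10,
                          weighted_cv = TRUE,
                          rating_cap = 90,
                          write_traces = FALSE) {
  if (is.list(design) && !inherits(design, "task_design")) {
    design <- do.call(task_design, design)
  }
  if (!is.null(coupling) && is.null(coupling$force_slope_vs_symptom)) {
    coupling <- do.call(cohort_coupling, coupling)
  }
  cfg <- list(
    n_participants = n_participants, seed = seed, design = design,
    coupling = coupling, population = population,
    miscalibrate = miscalibrate, input_dir = input_dir,
    sd_threshold = sd_threshold, outcome_mode = outcome_mode,
    huber_k = huber_k, lambda = lambda, cv_k = cv_k,
    weighted_cv = weighted_cv, rating_cap = rating_cap,
    write_traces = write_traces
  )
  class(cfg) <- "effort_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [effort_config()] arguments; `design`, `coupling`,
#' and `population` may be nested override maps.
#'
#' @param path YAML file path.
#' @return An `effort_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(effort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "effortsens_config_error")
  }
  if (!is.null(raw$design)) raw$design <- do.call(task_design, raw$design)
  if (!is.null(raw$coupling)) raw$coupling <- do.call(cohort_coupling, raw$coupling)
  if (!is.null(raw$population)) raw$population <- do.call(cohort_population, raw$population)
  do.call(effort_config, raw)
}

pipeline_log <- function(lines, log_path, quiet) {
  if (!quiet) message(paste(lines, collapse = "\n"))
  cat(lines, file = log_path, sep = "\n", append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> feature extraction -> link
#' selection -> sensitivity estimation and symptom regression -> two-step
#' ridge, writing each stage's tabular output plus a `report.md` summary to
#' `out_dir`. Every stage logs its inputs, parameters, and row counts to
#' `run.log`; the config hash is recorded in every report so outputs can be
#' traced to their configuration.
#'
#' @param config An [effort_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return A list of class `effort_run` with all stage results:
#'   `cohort`, `preprocessed`, `features`, `link`, `sensitivities`,
#'   `group_model`, `intercept_analysis`, `auc_sensitivities`, `ridge`,
#'   `ridge_summary`, `feature_cor`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = effort_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "effort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  cfg_hash <- rlang::hash(config)
  pipeline_log(c("effortsens pipeline", paste0("config hash: ", cfg_hash)),
               log_path, quiet)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "effortsens_pipeline_error", parent = e)
    })
  }

  # --- stage 1: cohort ------------------------------------------------
  cohort <- step("cohort", {
    if (!is.null(config$input_dir)) {
      read_cohort(config$input_dir, design = config$design)
    } else {
      generate_cohort(
        config$n_participants, design = config$design,
        coupling = config$coupling, population = config$population,
        miscalibrate = config$miscalibrate, seed = config$seed,
        outcome_mode = config$outcome_mode
      )
    }
  })
  pipeline_log(sprintf("cohort: %d participants, %d trials",
                       nrow(cohort$participants), nrow(cohort$trials)),
               log_path, quiet)
  write_cohort(cohort, out_dir, traces = config$write_traces)

  # --- stage 2: preprocessing ----------------------------------------
  prep <- step("preprocess",
               preprocess_cohort(cohort, sd_threshold = config$sd_threshold))
  pipeline_log(sprintf(
    "preprocess: %d -> %d (top-quartile MVC ratio) -> %d (outliers/all-success)",
    prep$counts["input"], prep$counts["after_quartile"],
    prep$counts["after_outliers"]), log_path, quiet)
  readr::write_csv(prep$exclusions, file.path(out_dir, "exclusions.csv"))

  # --- stage 3: features ---------------------------------------------
  features <- step("features", build_cohort_features(prep$cohort))
  pipeline_log(sprintf("features: %d rows x %d columns", nrow(features),
                       ncol(features)), log_path, quiet)
  readr::write_csv(features, file.path(out_dir, "features.csv"))

  # --- stage 4: link selection ---------------------------------------
  link <- step("link_selection", fit_link_models(prep$cohort$trials))
  sel <- attr(link, "selected")
  pipeline_log(sprintf("link selection: %s link, %s random effects",
                       sel$link, sel$random_effects), log_path, quiet)
  readr::write_csv(tibble::as_tibble(link),
                   file.path(out_dir, "link_comparison.csv"))

  # --- stage 5: sensitivities + symptom associations -----------------
  force_col <- if (sel$link == "quadratic") "target_force_sq" else "target_force"
  sens <- step("sensitivity",
               fit_cohort_sensitivities(features, force_col = force_col,
                                        k = config$huber_k))
  group <- step("group_regression",
                fit_group_regression(sens, prep$cohort$participants))
  icpt <- step("intercept_analysis",
               intercept_symptom_analysis(features, prep$cohort$participants,
                                          rating_cap = config$rating_cap,
                                          force_col = force_col,
                                          k = config$huber_k))
  auc_sens <- step("auc_sensitivity",
                   actual_force_sensitivity(features, k = config$huber_k,
                                            on_error = "drop"))
  pipeline_log(sprintf("sensitivity: %d participants; intercept-PHQ9 r = %.3f (cap %g)",
                       nrow(sens), icpt$r, icpt$rating_cap), log_path, quiet)
  readr::write_csv(sens, file.path(out_dir, "sensitivities.csv"))
  jsonlite::write_json(
    list(coefficients = tibble::as_tibble(group), n = attr(group, "n"),
         config_hash = cfg_hash),
    file.path(out_dir, "group_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # --- stage 6: two-step ridge ---------------------------------------
  ridge <- step("ridge",
                fit_cohort_ridge(features, lambda = config$lambda,
                                 k_folds = config$cv_k, seed = config$seed,
                                 weighted_cv = config$weighted_cv,
                                 k = config$huber_k))
  ridge_summary <- summarize_group(ridge)
  fcor <- feature_correlations(features)
  pipeline_log(sprintf("ridge: %d participants, median lambda %.3g",
                       nrow(ridge$betas), median(ridge$betas$lambda)),
               log_path, quiet)
  readr::write_csv(ridge$betas, file.path(out_dir, "ridge_betas.csv"))
  readr::write_csv(
    tibble::as_tibble(fcor, rownames = "feature"),
    file.path(out_dir, "feature_correlations.csv")
  )

  # --- report ---------------------------------------------------------
  sym <- tibble::as_tibble(group)
  sym <- sym[!is.na(sym$q_value), ]
  report <- c(
    "# effortsens pipeline report", "",
    paste0("config hash: `", cfg_hash, "`  |  seed: ", config$seed), "",
    "## Cohort and exclusions", "",
    sprintf("- participants in: %d", prep$counts["input"]),
    sprintf("- retained after top-quartile MVC-ratio exclusion: %d",
            prep$counts["after_quartile"]),
    sprintf("- retained after outlier / all-success exclusions: %d",
            prep$counts["after_outliers"]), "",
    "## Link selection", "",
    sprintf("- selected: **%s** link with **%s** random effects",
            sel$link, sel$random_effects), "",
    "## Symptom associations (standardised betas)", "",
    sprintf("- %s ~ %s: beta = %.3f, p = %.4f, q = %.4f",
            sym$outcome, sym$term, sym$estimate, sym$p_value, sym$q_value),
    sprintf("- intercept ~ PHQ9 correlation: r = %.3f (p = %.4f, rating cap %g)",
            icpt$r, icpt$p_value, icpt$rating_cap), "",
    "## Ridge feature summary (mean standardised beta, 95% CI)", "",
    sprintf("- %s: %.3f [%.3f, %.3f]", ridge_summary$term,
            ridge_summary$mean, ridge_summary$ci_lo, ridge_summary$ci_hi)
  )
  writeLines(report, file.path(out_dir, "report.md"))

  structure(
    list(cohort = cohort, preprocessed = prep, features = features,
         link = link, sensitivities = sens, group_model = group,
         intercept_analysis = icpt, auc_sensitivities = auc_sens,
         ridge = ridge, ridge_summary = ridge_summary, feature_cor = fcor,
         config = config, config_hash = cfg_hash, out_dir = out_dir),
    class = "effort_run"
  )
}

#' @export
print.effort_run <- function(x, ...) {
  cat("<effort_run>\n")
  cat(sprintf("  counts: %d -> %d -> %d\n",
              x$preprocessed$counts["input"],
              x$preprocessed$counts["after_quartile"],
              x$preprocessed$counts["after_outliers"]))
  sel <- attr(x$link, "selected")
  cat(sprintf("  link: %s / %s\n", sel$link, sel$random_effects))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
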