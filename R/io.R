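#' Write a cohort to plain-text files
#'
#' Writes `participants.csv` (covariates, MVCs, symptom scores, and any
#' `sim_*` generative columns), `trials.csv` (design values, outcome,
#' rating, and the trace sampling rate), `traces.csv` (long table keyed by
#' participant and trial: `time_s`, `force`), and `schema.json` (column
#' dictionary with units).
#'
#' @param cohort An `effort_cohort`.
#' @param dir Output directory (created if needed).
#' @param traces Include the force traces (default `TRUE`; they dominate
#'   file size).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, traces = TRUE) {
  stopifnot(inherits(cohort, "effort_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  trials <- cohort$trials
  trials$sample_rate_hz <- vapply(
    trials$trace, function(tr) if (inherits(tr, "force_trace")) tr$sample_rate_hz else NA_real_,
    numeric(1)
  )
  readr::write_csv(dplyr::select(trials, -"trace"), file.path(dir, "trials.csv"))
  if (traces) {
    long <- purrr::pmap_dfr(
      list(trials$participant_id, trials$trial_index, trials$trace),
      function(pid, idx, tr) {
        tb <- as_tibble.force_trace(tr)
        tibble::tibble(participant_id = pid, trial_index = idx,
                       time_s = tb$time_s, force = tb$force)
      }
    )
    readr::write_csv(long, file.path(dir, "traces.csv"))
  }
  schema <- list(
    participants = list(
      id = "participant label", age = "years", sex = "1 = female, 0 = male",
      dominant_hand = "right/left", mvc_dom = "newtons", mvc_nondom = "newtons",
      phq9 = "PHQ9 total, 0-27", aes = "AES total, 18-72",
      sim_columns = "generative parameters (simulated cohorts only)"
    ),
    trials = list(
      target_force_frac = "fraction of the squeezing hand's MVC",
      band_lo = "fraction of MVC", band_hi = "fraction of MVC",
      outcome = "1 = failure, 0 = success",
      time_in_band_s = "seconds", rating = "0-100 visual-analogue",
      sample_rate_hz = "Hz"
    ),
    traces = list(time_s = "seconds from trial start",
                  force = "fraction of the squeezing hand's MVC")
  )
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

read_checked_csv <- function(path, required = character(0)) {
  if (!file.exists(path)) {
    abort(paste0("Missing file: ", path), class = "effortsens_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed cell(s) in ", basename(path), ": ",
      paste(sprintf("row %d col %d (%s)", probs$row, probs$col, probs$expected),
            collapse = "; ")
    ), class = "effortsens_io_error")
  }
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0(basename(path), " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "effortsens_io_error")
  }
  tab
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]. Unknown extra columns are preserved
#' untouched; malformed numeric cells and missing required columns raise
#' errors naming the offending file, row, and column.
#'
#' @param dir Directory containing `participants.csv`, `trials.csv`, and
#'   optionally `traces.csv`.
#' @param design A [task_design()] recorded with the cohort (defaults to the
#'   standard design).
#' @return An `effort_cohort`.
#' @export
read_cohort <- function(dir, design = task_design()) {
  participants <- read_checked_csv(
    file.path(dir, "participants.csv"),
    required = c("id", "mvc_dom", "mvc_nondom", "phq9", "aes", "sex", "age")
  )
  trials <- read_checked_csv(
    file.path(dir, "trials.csv"),
    required = c("participant_id", "trial_index", "hand", "target_force_frac",
                 "band_lo", "band_hi", "outcome", "rating")
  )
  traces_path <- file.path(dir, "traces.csv")
  if (file.exists(traces_path)) {
    long <- read_checked_csv(
      traces_path,
      required = c("participant_id", "trial_index", "time_s", "force")
    )
    rate_tab <- if ("sample_rate_hz" %in% names(trials)) {
      setNames(trials$sample_rate_hz,
               paste(trials$participant_id, trials$trial_index))
    } else {
      NULL
    }
    nested <- long |>
      dplyr::group_by(.data$participant_id, .data$trial_index) |>
      dplyr::group_split()
    key <- vapply(nested, function(g) {
      paste(g$participant_id[1], g$trial_index[1])
    }, character(1))
    trace_objs <- lapply(nested, function(g) {
      rate <- if (!is.null(rate_tab)) {
        rate_tab[[paste(g$participant_id[1], g$trial_index[1])]]
      } else if (nrow(g) > 1) {
        1 / (g$time_s[2] - g$time_s[1])
      } else {
        design$sample_rate_hz
      }
      force_trace(g$force, sample_rate_hz = rate)
    })
    trials$trace <- trace_objs[match(
      paste(trials$participant_id, trials$trial_index), key)]
  }
  structure(
    list(participants = participants, trials = trials, design = design),
    class = "effort_cohort"
  )
}
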