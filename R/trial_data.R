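# Long-format trial tables for the three-condition heat-pain rating task:
# TSV input/output, validation, and the descriptive summaries used throughout
# the analysis.

#' Canonical column order of a trial table
#'
#' One row per trial: `subject_id` (label), `session` (1 or 2; repetition of
#' the condition), `run` (1..6), `trial` (1..15, position within run),
#' `condition` (`"C"` controllable, `"P"` predictable, `"U"` unpredictable),
#' `intensity_level` (VAS target 30/50/70), `rating` (0-100 or `NA` for a
#' timeout), `reaction_time` (seconds), `chosen` (`TRUE` only on controllable
#' trials).
#'
#' @return Character vector of column names in file order.
#' @export
trial_columns <- function() {
  c("subject_id", "session", "run", "trial", "condition",
    "intensity_level", "rating", "reaction_time", "chosen")
}

.condition_levels <- c("C", "P", "U")
.intensity_levels <- c(30, 50, 70)

#' Validate a trial table
#'
#' Checks per-row ranges (rating in `[0, 100]`, trial in 1..15, condition and
#' intensity levels from the task design) and the schedule invariants: each
#' intensity level occurs exactly five times per run and the condition is
#' constant within a run. The full design (six runs per subject, two per
#' condition, 90 trials) is checked softly: breaches give a warning so
#' partial datasets remain usable.
#'
#' @param data A trial tibble (see [trial_columns()]).
#' @param strict If `TRUE` (default) invariant breaches raise an error;
#'   otherwise they warn.
#' @return `data`, invisibly coerced to a tibble with canonical column order.
#' @export
validate_trials <- function(data, strict = TRUE) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(trial_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("Trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[trial_columns()]
  breaches <- character()

  bad_rating <- which(!is.na(data$rating) &
                        (data$rating < 0 | data$rating > 100))
  if (length(bad_rating) > 0) {
    breaches <- c(breaches, paste0(
      "rating out of [0,100] in row(s) ",
      paste(head(bad_rating, 5), collapse = ", ")))
  }
  if (!all(data$condition %in% .condition_levels)) {
    breaches <- c(breaches, "condition outside {C, P, U}")
  }
  if (!all(data$intensity_level %in% .intensity_levels)) {
    breaches <- c(breaches, "intensity_level outside {30, 50, 70}")
  }
  if (!all(data$trial %in% 1:15)) {
    breaches <- c(breaches, "trial outside 1..15")
  }
  if (any(!is.na(data$reaction_time) & data$reaction_time < 0)) {
    breaches <- c(breaches, "negative reaction_time")
  }

  per_run <- dplyr::group_by(data, .data$subject_id, .data$run)
  run_check <- dplyr::summarise(
    per_run,
    one_condition = dplyr::n_distinct(.data$condition) == 1,
    balanced = all(table(factor(.data$intensity_level,
                                levels = .intensity_levels)) == 5) &&
      dplyr::n() == 15,
    .groups = "drop")
  if (!all(run_check$one_condition)) {
    breaches <- c(breaches, "condition not constant within a run")
  }
  if (!all(run_check$balanced)) {
    bad <- run_check[!run_check$balanced, ]
    breaches <- c(breaches, paste0(
      "run without exactly 5 trials per intensity level (subject ",
      paste(unique(bad$subject_id), collapse = ", "), ")"))
  }

  if (length(breaches) > 0) {
    msg <- paste0("Trial table validation failed:\n  - ",
                  paste(breaches, collapse = "\n  - "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  design <- dplyr::summarise(
    dplyr::group_by(data, .data$subject_id),
    n_runs = dplyr::n_distinct(.data$run),
    n_trials = dplyr::n(),
    two_per_condition = all(table(factor(
      .data$condition[!duplicated(.data$run)],
      levels = .condition_levels)) == 2),
    .groups = "drop")
  incomplete <- design$n_runs != 6 | design$n_trials != 90 |
    !design$two_per_condition
  if (any(incomplete)) {
    warning("Incomplete design (expected 6 runs / 90 trials / 2 runs per ",
            "condition) for subject(s): ",
            paste(design$subject_id[incomplete], collapse = ", "),
            call. = FALSE)
  }
  invisible(data)
}

#' Read a long-format trial table from TSV
#'
#' @param path Path to a tab-separated file whose header names the columns of
#'   [trial_columns()]. Missing values are encoded as `NA`.
#' @param strict Passed to [validate_trials()].
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, strict = TRUE) {
  data <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      session = readr::col_integer(),
      run = readr::col_integer(),
      trial = readr::col_integer(),
      condition = readr::col_character(),
      intensity_level = readr::col_double(),
      rating = readr::col_double(),
      reaction_time = readr::col_double(),
      chosen = readr::col_logical()
    ),
    na = "NA", progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop("Malformed TSV at line(s) ",
         paste(unique(probs$row), collapse = ", "), ": ",
         probs$expected[1], " expected, got ", probs$actual[1],
         call. = FALSE)
  }
  validate_trials(data, strict = strict)
  data[trial_columns()]
}

#' Write a trial table to TSV
#'
#' Writes the canonical column order with missing values encoded as `"NA"`,
#' so that `read_trials(write_trials(x))` round-trips exactly.
#'
#' @param data Trial tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_trials <- function(data, path) {
  missing_cols <- setdiff(trial_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("Trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(data[trial_columns()], path, na = "NA", progress = FALSE)
  invisible(data)
}

#' Within-subject standard deviations of pain ratings
#'
#' The sample standard deviation (n - 1 denominator) of the ratings in each
#' subject x condition x intensity cell (nominally 10 ratings: 5 per run, 2
#' runs per condition). Cells with fewer than two observed ratings yield
#' `NA`. These SDs are the outcome of the rating-variability mixed model and
#' a behavioural proxy for expectation precision.
#'
#' @param data Trial tibble.
#' @return Tibble with `subject_id`, `condition`, `intensity_level`, `sd`,
#'   `n` (count of non-missing ratings).
#' @export
within_subject_sd_table <- function(data) {
  data |>
    dplyr::group_by(.data$subject_id, .data$condition,
                    .data$intensity_level) |>
    dplyr::summarise(
      sd = ifelse(sum(!is.na(.data$rating)) >= 2,
                  stats::sd(.data$rating, na.rm = TRUE), NA_real_),
      n = sum(!is.na(.data$rating)),
      .groups = "drop")
}

#' Choice percentages by trial position
#'
#' For controllable runs, the percentage of choices of each intensity level
#' at each within-run trial position (1..15), pooled over subjects and runs.
#' Percentages at a position sum to 100.
#'
#' @param data Trial tibble.
#' @return Tibble with `trial`, `intensity_level`, `percent`; empty if no
#'   chosen controllable trials exist.
#' @export
choice_percentages <- function(data) {
  ch <- dplyr::filter(data, .data$condition == "C", .data$chosen %in% TRUE)
  if (nrow(ch) == 0) {
    return(tibble::tibble(trial = integer(), intensity_level = double(),
                          percent = double()))
  }
  ch |>
    dplyr::count(.data$trial, intensity_level = factor(
      .data$intensity_level, levels = .intensity_levels)) |>
    tidyr::complete(.data$trial, .data$intensity_level,
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(intensity_level = as.numeric(
      as.character(.data$intensity_level))) |>
    dplyr::select("trial", "intensity_level", "percent")
}

#' Reaction-time summary per condition
#'
#' Plain mean and standard deviation of the non-missing reaction times in
#' each condition. Controllable trials involve a deliberate choice and are
#' expected to be slower than the colour-matching trials.
#'
#' @param data Trial tibble.
#' @return Tibble with `condition`, `mean_rt`, `sd_rt`, `n`.
#' @export
rt_summary <- function(data) {
  data |>
    dplyr::filter(!is.na(.data$reaction_time)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_rt = mean(.data$reaction_time),
                     sd_rt = stats::sd(.data$reaction_time),
                     n = dplyr::n(), .groups = "drop")
}
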