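.schema_cols <- c(
  "subject_id", "group", "day_index", "day_of_week", "day_type",
  "sleep_quality",
  paste0("mood_", 1:3), paste0("stress_", 1:3),
  paste0("energy_", 1:3), paste0("focus_", 1:3),
  "activity_minutes", "mean_temp", "clear_sky_minutes", "phq9", "gad7"
)
.likert_cols <- c("sleep_quality", paste0("mood_", 1:3), paste0("stress_", 1:3),
                  paste0("energy_", 1:3), paste0("focus_", 1:3))

#' Read a long-format daily EMA panel from CSV
#'
#' Reads the panel schema written by [write_cohort()] (also produced by real
#' diary exports): one row per subject-day with the raw within-day ratings.
#' Empty fields become `NA`; schema and range violations are rejected.
#'
#' @param path CSV path.
#' @param aggregate If `TRUE` (default), collapse the within-day rating
#'   triples to daily means via [aggregate_daily()].
#' @return A subject-day tibble.
#' @export
read_panel_csv <- function(path, aggregate = TRUE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  missing_cols <- setdiff(.schema_cols, names(raw))
  if (length(missing_cols))
    abort(sprintf("panel schema error: missing column(s) %s",
                  paste0("`", missing_cols, "`", collapse = ", ")),
          class = "sleepmood_schema_error")
  validate_panel(raw)
  if (aggregate) aggregate_daily(raw) else raw
}

validate_panel <- function(raw) {
  for (cl in .likert_cols) {
    v <- raw[[cl]]
    bad <- which(!is.na(v) & (v < 0 | v > 8 | v != floor(v)))
    if (length(bad))
      abort(sprintf(
        "validation error: column `%s` has a value outside the 0-8 Likert scale at row %d",
        cl, bad[[1]]), class = "sleepmood_validation_error")
  }
  bad_dt <- which(!is.na(raw$day_type) &
                    !raw$day_type %in% c("normal", "partial", "off"))
  if (length(bad_dt))
    abort(sprintf("validation error: unknown `day_type` at row %d", bad_dt[[1]]),
          class = "sleepmood_validation_error")
  nondec <- raw |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = all(diff(.data$day_index) > 0), .groups = "drop")
  if (any(!nondec$ok))
    abort(sprintf(
      "validation error: `day_index` not strictly increasing for subject %s",
      nondec$subject_id[!nondec$ok][[1]]), class = "sleepmood_validation_error")
  invisible(raw)
}

#' Collapse within-day rating triples to daily values
#'
#' Mood, stress, energy, and focus are each rated up to three times a day;
#' the daily value is the arithmetic mean of the available ratings, or `NA`
#' when all three are absent. Sleep quality is a single morning item and
#' passes through.
#'
#' @param raw A raw subject-day tibble in the panel schema.
#' @return A tibble with columns `mood`, `stress`, `energy`, `focus`
#'   replacing the rating triples.
#' @examples
#' # mean of available ratings: (4, 5, 6) -> 5; (7, NA, NA) -> 7
#' @export
aggregate_daily <- function(raw) {
  day_mean <- function(prefix) {
    m <- as.matrix(raw[, paste0(prefix, "_", 1:3)])
    out <- rowMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  raw |>
    dplyr::mutate(
      mood = day_mean("mood"), stress = day_mean("stress"),
      energy = day_mean("energy"), focus = day_mean("focus"),
      .after = "sleep_quality"
    ) |>
    dplyr::select(-dplyr::all_of(setdiff(.likert_cols, "sleep_quality")))
}

#' Within-person z-score normalization
#'
#' Replaces each listed variable, per subject, by
#' `(x - subject mean) / subject SD` (sample SD, n - 1 denominator).
#' Subjects with zero SD (or fewer than two observed values) of a variable
#' cannot be normalized: their values become `NA` and the subject-variable
#' pair is recorded in the `zero_sd` attribute so it is flagged, not
#' silently dropped.
#'
#' @param data A tibble with a `subject_id` column.
#' @param vars Character vector of columns to normalize.
#' @return `data` with the variables replaced by z-scores; attribute
#'   `zero_sd` is a tibble of flagged (subject_id, variable) pairs.
#' @examples
#' # z-scores of (2, 4, 6) are (-1, 0, 1): the sample SD is 2
#' @export
znormalize_within_subject <- function(data, vars) {
  stopifnot("subject_id" %in% names(data), all(vars %in% names(data)))
  flagged <- list()
  out <- data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), zscore)) |>
    dplyr::ungroup()
  for (v in vars) {
    per <- data |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        degenerate = sum(!is.na(.data[[v]])) < 2L ||
          isTRUE(stats::sd(.data[[v]], na.rm = TRUE) == 0),
        .groups = "drop")
    if (any(per$degenerate))
      flagged[[v]] <- tibble::tibble(
        subject_id = per$subject_id[per$degenerate], variable = v)
  }
  attr(out, "zero_sd") <- if (length(flagged)) dplyr::bind_rows(flagged) else
    tibble::tibble(subject_id = character(), variable = character())
  # carry over lag metadata if present
  for (a in c("direction", "history_depth", "confounder_timing"))
    attr(out, a) <- attr(data, a)
  out
}

#' Exclude subjects with near-constant treatment series
#'
#' Subjects whose raw (pre-normalization, pre-binarization) daily treatment
#' variance falls strictly below the threshold do not admit a reliable
#' above/below-mean treatment discretization and are excluded from the
#' matching analyses. The sample variance (n - 1 denominator) is used.
#'
#' @param daily A daily panel tibble (see [aggregate_daily()]).
#' @param variable The treatment variable for the current direction
#'   (`"sleep_quality"` or `"mood"`).
#' @param threshold Exclusion threshold; the rule is strict `<`. Default 0.5.
#' @return A list with `kept` (the filtered panel) and `excluded`
#'   (tibble of `subject_id`, `variance`).
#' @export
filter_low_variance <- function(daily, variable, threshold = 0.5) {
  stopifnot(variable %in% names(daily))
  pv <- daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(variance = stats::var(.data[[variable]], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(variance = ifelse(is.na(.data$variance), 0, .data$variance))
  excl <- pv |> dplyr::filter(.data$variance < threshold)
  list(
    kept = daily |> dplyr::filter(!.data$subject_id %in% excl$subject_id),
    excluded = excl
  )
}
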