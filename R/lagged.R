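#' Build a directional lagged day-pair dataset
#'
#' Pairs each subject's treatment and outcome days for one causal direction:
#'
#' * `sleep_to_mood`: treatment is the sleep quality reported on the morning
#'   of day *t* (the night ending that morning), outcome is the mean mood of
#'   day *t*.
#' * `mood_to_sleep`: treatment is the mean mood of day *t*, outcome is the
#'   sleep quality reported on the morning of day *t + 1*.
#'
#' Each row also carries the confounder vector: stress, energy, focus,
#' activity, temperature, and clear-sky minutes taken from the day before the
#' outcome day (switchable to the day before the treatment day), the day of
#' week and day type of that same day, and, for history depth `T >= 1`, the
#' mood and sleep quality 1..T days before the treatment day. Any required
#' day that is absent from the diary, or any required value that is `NA`,
#' drops the row — lags must span consecutive calendar days and nothing is
#' imputed.
#'
#' @param daily A daily panel tibble (see [aggregate_daily()]).
#' @param direction `"sleep_to_mood"` or `"mood_to_sleep"`.
#' @param T History depth, 0-3: how many preceding days of both series enter
#'   the confounder vector.
#' @param confounder_timing `"before_outcome"` (default) or
#'   `"before_treatment"`; the two differ only for `mood_to_sleep`.
#' @param require_confounders If `FALSE`, only the treatment/outcome pairing
#'   is required (used for the unmatched comparator, which uses all paired
#'   days regardless of confounder availability).
#' @return A tibble with columns `subject_id`, `group`, `outcome_day`,
#'   `treatment`, `outcome`, the confounder columns, and `mood_lag1..T`,
#'   `sleep_lag1..T`; attributes `direction`, `history_depth`,
#'   `confounder_timing`.
#' @export
build_lagged_dataset <- function(daily, direction, T = 0,
                                 confounder_timing = c("before_outcome",
                                                       "before_treatment"),
                                 require_confounders = TRUE) {
  direction <- match_direction(direction)
  confounder_timing <- match.arg(confounder_timing)
  if (!T %in% 0:3) stop_field("T", "history depth must be one of 0, 1, 2, 3")

  need <- c("subject_id", "day_index", "sleep_quality", "mood",
            .confounder_num, .confounder_cat)
  stopifnot(all(need %in% names(daily)))
  if (!"group" %in% names(daily)) daily$group <- NA_character_

  one_subject <- function(d, ...) {
    d <- dplyr::arrange(d, .data$day_index)
    # complete the calendar so dplyr::lag/lead are true day offsets
    full <- tidyr::complete(
      d, day_index = seq(min(d$day_index), max(d$day_index)))
    full <- dplyr::arrange(full, .data$day_index)
    conf_off <- if (direction == "sleep_to_mood" ||
                    confounder_timing == "before_treatment") 1L else 0L
    out <- full |>
      dplyr::mutate(
        treatment = if (direction == "sleep_to_mood") .data$sleep_quality else
          .data$mood,
        outcome = if (direction == "sleep_to_mood") .data$mood else
          dplyr::lead(.data$sleep_quality, 1L),
        outcome_day = if (direction == "sleep_to_mood") .data$day_index else
          .data$day_index + 1L,
        dplyr::across(dplyr::all_of(c(.confounder_num, .confounder_cat)),
                      ~ dplyr::lag(.x, conf_off))
      )
    for (k in seq_len(T)) {
      out[[paste0("mood_lag", k)]] <- dplyr::lag(full$mood, k)
      out[[paste0("sleep_lag", k)]] <- dplyr::lag(full$sleep_quality, k)
    }
    keep_cols <- c("outcome_day", "treatment", "outcome",
                   .confounder_num, .confounder_cat,
                   if (T > 0) paste0(rep(c("mood_lag", "sleep_lag"), T),
                                     rep(seq_len(T), each = 2)))
    out <- out[, c("group", keep_cols)]
    required <- c("treatment", "outcome",
                  if (require_confounders)
                    setdiff(keep_cols, c("outcome_day", "treatment", "outcome")))
    complete <- stats::complete.cases(out[, required])
    out[complete, , drop = FALSE]
  }

  res <- daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(one_subject) |>
    dplyr::ungroup()
  attr(res, "direction") <- direction
  attr(res, "history_depth") <- T
  attr(res, "confounder_timing") <- confounder_timing
  res
}
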