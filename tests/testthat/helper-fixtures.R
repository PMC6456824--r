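# fixtures are built in code from the package's own generator

sim_daily <- function(n_per_group = 3, n_days = 12, seed = 1, ...) {
  aggregate_daily(simulate_cohort(sim_config(
    n_subjects_per_group = n_per_group, n_days = n_days, seed = seed, ...)))
}

# a minimal hand-built daily panel: one subject, chosen day indices, all
# confounders present and mildly varying
hand_daily <- function(day_index, sleep, mood, subject_id = "S001") {
  n <- length(day_index)
  tibble::tibble(
    subject_id = subject_id, group = "control", day_index = day_index,
    day_of_week = ((day_index - 1) %% 7) + 1,
    day_type = rep(c("normal", "off", "partial"), length.out = n),
    sleep_quality = sleep, mood = mood,
    stress = seq(2, 6, length.out = n), energy = rev(seq(2, 6, length.out = n)),
    focus = seq(1, 5, length.out = n),
    activity_minutes = 30 + 5 * seq_len(n),
    mean_temp = 10 + seq_len(n), clear_sky_minutes = 100 * seq_len(n) %% 400,
    phq9 = 4L, gad7 = 3L
  )
}

# raw-schema (rating triples) panel writer for read_panel_csv tests
raw_panel_rows <- function(n_subjects = 3, n_days = 5) {
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    tibble::tibble(
      subject_id = sprintf("P%02d", i), group = "control",
      day_index = seq_len(n_days), day_of_week = ((seq_len(n_days) - 1) %% 7) + 1,
      day_type = "normal",
      sleep_quality = (seq_len(n_days) + i) %% 9,
      mood_1 = (seq_len(n_days) + i) %% 9, mood_2 = (seq_len(n_days) + i + 1) %% 9,
      mood_3 = (seq_len(n_days) + i + 2) %% 9,
      stress_1 = 4L, stress_2 = 5L, stress_3 = 3L,
      energy_1 = 4L, energy_2 = 4L, energy_3 = 5L,
      focus_1 = 6L, focus_2 = 5L, focus_3 = 4L,
      activity_minutes = 30L + i, mean_temp = 12.5, clear_sky_minutes = 240L,
      phq9 = 4L, gad7 = 3L
    )
  })
}
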