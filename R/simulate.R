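#' Simulate one subject's daily diary panel
#'
#' Generates a coupled latent bivariate day process and maps it to observed
#' 0-8 Likert ratings through the subject's reporting style. The latent
#' dynamics are
#' \deqn{mood_t = ar_m mood_{t-1} + \beta_{s \to m} sleep_t + s\, c_t + \epsilon_t}
#' \deqn{sleep_{t+1} = ar_s sleep_t + \beta_{m \to s} mood_t + s\, c_t + \epsilon'_t}
#' where `sleep_t` is the quality of the night reported on the morning of day
#' `t`, and `c_t` is a shared standard-normal daily confounder that is also
#' emitted, with independent noise, as the observable stress, energy, and
#' focus ratings. Mood, stress, energy, and focus are each rated three times a
#' day; sleep quality once. Weather, physical activity, day of week, and day
#' type are generated as exogenous covariates.
#'
#' @param style A [reporting_style()].
#' @param group A [group_label()].
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Identifier stored in the `subject_id` column.
#' @return A tibble with one row per diary day, in the long panel schema
#'   (see [write_cohort()]), plus dot-prefixed latent columns
#'   (`.latent_mood`, `.latent_sleep`, `.latent_conf`) retained for
#'   validation and dropped on export.
#' @export
simulate_subject <- function(style, group, config, subject_seed,
                             subject_id = "S001") {
  validate_sim_config(config)
  stopifnot(inherits(style, "reporting_style"), inherits(group, "group_label"))
  n <- config$n_days
  b_sm <- config$beta_sleep_to_mood
  b_ms <- config$beta_mood_to_sleep
  if (!is.null(config$group_effects[[group$name]])) {
    ov <- config$group_effects[[group$name]]
    b_sm <- ov$beta_sleep_to_mood %||% b_sm
    b_ms <- ov$beta_mood_to_sleep %||% b_ms
  }
  with_seed(subject_seed, {
    ar_m <- config$ar_mood; ar_s <- config$ar_sleep
    cs <- config$confounder_strength; ns <- config$noise_sd
    conf <- rnorm(n)
    lm_ <- ls_ <- numeric(n)
    ls_[1] <- rnorm(1, 0, ns / sqrt(1 - ar_s^2))
    lm_[1] <- b_sm * ls_[1] + cs * conf[1] + rnorm(1, 0, ns)
    for (t in seq_len(n)[-1]) {
      # the night between day t-1 and day t receives day t-1's confounder
      ls_[t] <- ar_s * ls_[t - 1] + b_ms * lm_[t - 1] + cs * conf[t - 1] +
        rnorm(1, 0, ns)
      lm_[t] <- ar_m * lm_[t - 1] + b_sm * ls_[t] + cs * conf[t] +
        rnorm(1, 0, ns)
    }

    likert <- function(x) {
      pmin(8, pmax(0, round_half_up(4 + style$scale * x + style$shift)))
    }
    triple <- function(latent) {
      lapply(1:3, function(k) likert(latent + rnorm(n, 0, config$report_sd)))
    }
    # stress/energy/focus are noisy daily reflections of the same confounder
    construct_latent <- function() conf + rnorm(n, 0, 0.35)
    mood_r <- triple(lm_)
    stress_r <- triple(construct_latent())
    energy_r <- triple(construct_latent())
    focus_r <- triple(construct_latent())

    start_dow <- sample.int(7, 1)
    dow <- ((start_dow + seq_len(n) - 2L) %% 7L) + 1L
    weekend <- dow >= 6L
    day_type <- ifelse(
      weekend,
      sample(c("off", "partial", "normal"), n, TRUE, prob = c(0.8, 0.1, 0.1)),
      sample(c("normal", "partial", "off"), n, TRUE, prob = c(0.8, 0.1, 0.1))
    )
    doy0 <- runif(1, 0, 365)
    gname <- group$name; phq9_i <- group$phq9; gad7_i <- group$gad7
    tibble::tibble(
      subject_id = subject_id,
      group = gname,
      day_index = seq_len(n),
      day_of_week = dow,
      day_type = day_type,
      sleep_quality = likert(ls_ + rnorm(n, 0, config$report_sd)),
      mood_1 = mood_r[[1]], mood_2 = mood_r[[2]], mood_3 = mood_r[[3]],
      stress_1 = stress_r[[1]], stress_2 = stress_r[[2]], stress_3 = stress_r[[3]],
      energy_1 = energy_r[[1]], energy_2 = energy_r[[2]], energy_3 = energy_r[[3]],
      focus_1 = focus_r[[1]], focus_2 = focus_r[[2]], focus_3 = focus_r[[3]],
      activity_minutes = round_half_up(rgamma(n, shape = 1.5, scale = 40)),
      mean_temp = round(12 + 9 * sin(2 * pi * (doy0 + seq_len(n)) / 365) +
                          rnorm(n, 0, 3), 1),
      clear_sky_minutes = round_half_up(720 * rbeta(n, 1.5, 1.5)),
      phq9 = phq9_i,
      gad7 = gad7_i,
      .latent_mood = lm_,
      .latent_sleep = ls_,
      .latent_conf = conf
    )
  })
}

#' Simulate a four-group EMA cohort with known ground truth
#'
#' Draws, for each of the four symptom groups, `n_subjects_per_group`
#' subjects: screening scores from group-specific truncated normals honouring
#' the PHQ-9/GAD-7 >= 10 cutoffs, a subject reporting style, the coupled
#' latent diary process, and finally MCAR day-level missingness.
#'
#' @param config A [sim_config()].
#' @return A tibble of subject-days (the long panel schema) carrying a
#'   `truth` attribute: the config, the per-subject styles and seeds, and the
#'   effective cross-lag coefficients per group. Retrieve it with
#'   [cohort_truth()].
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects_per_group = 2, n_days = 10, seed = 1))
#' dplyr::n_distinct(cohort$subject_id)
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  subjects <- list(); panels <- list(); k <- 0L
  for (gi in seq_along(.group_names)) {
    gname <- .group_names[[gi]]
    sc <- .group_screening[[gname]]
    scores <- with_seed(derive_seed(config$seed, gi), list(
      phq9 = rtrunc_int(config$n_subjects_per_group, sc$phq9[1], sc$phq9[2],
                        sc$phq9_rng[1], sc$phq9_rng[2]),
      gad7 = rtrunc_int(config$n_subjects_per_group, sc$gad7[1], sc$gad7[2],
                        sc$gad7_rng[1], sc$gad7_rng[2])
    ))
    for (i in seq_len(config$n_subjects_per_group)) {
      k <- k + 1L
      sid <- sprintf("S%03d", k)
      sseed <- derive_seed(config$seed, gi * 100000L + i)
      style <- with_seed(derive_seed(sseed, 1L), reporting_style(
        shift = rnorm(1, 0, config$style_shift_sd),
        scale = exp(rnorm(1, log(1.3), config$style_scale_sdlog))
      ))
      grp <- group_label(gname, scores$phq9[i], scores$gad7[i])
      panel <- simulate_subject(style, grp, config,
                                subject_seed = derive_seed(sseed, 2L),
                                subject_id = sid)
      panel <- inject_missingness(panel, config$missing_prob,
                                  seed = derive_seed(sseed, 3L))
      panels[[k]] <- panel
      subjects[[k]] <- tibble::tibble(
        subject_id = sid, group = gname,
        phq9 = grp$phq9, gad7 = grp$gad7,
        shift = style$shift, scale = style$scale, subject_seed = sseed
      )
    }
  }
  cohort <- dplyr::bind_rows(panels)
  betas <- purrr::map(setNames(.group_names, .group_names), function(g) {
    ov <- config$group_effects[[g]]
    list(
      beta_sleep_to_mood = (ov$beta_sleep_to_mood %||% config$beta_sleep_to_mood),
      beta_mood_to_sleep = (ov$beta_mood_to_sleep %||% config$beta_mood_to_sleep)
    )
  })
  attr(cohort, "truth") <- list(
    config = unclass(config)[setdiff(names(config), "group_effects")],
    group_betas = betas,
    subjects = dplyr::bind_rows(subjects)
  )
  cohort
}

#' Ground truth attached to a simulated cohort
#'
#' @param cohort A tibble returned by [simulate_cohort()].
#' @return The `truth` attribute: config, per-group effective coefficients,
#'   and the per-subject style table.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Drop diary days completely at random
#'
#' Each day is removed independently with probability `missing_prob`; the
#' `day_index` of retained records is unchanged, so calendar gaps are
#' preserved for the downstream lag logic.
#'
#' @param panel A subject-day tibble (one or more subjects).
#' @param missing_prob Per-day drop probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The panel with rows removed.
#' @export
inject_missingness <- function(panel, missing_prob, seed) {
  if (!is.numeric(missing_prob) || missing_prob < 0 || missing_prob >= 1)
    stop_field("missing_prob", "must be in [0, 1)")
  if (missing_prob == 0) return(panel)
  with_seed(seed, {
    keep <- runif(nrow(panel)) >= missing_prob
    panel[keep, , drop = FALSE]
  })
}

#' Write a cohort to CSV (and its ground truth to YAML)
#'
#' The CSV is the package's long panel schema: one row per subject-day with
#' columns `subject_id, group, day_index, day_of_week, day_type,
#' sleep_quality, mood_1..3, stress_1..3, energy_1..3, focus_1..3,
#' activity_minutes, mean_temp, clear_sky_minutes, phq9, gad7`. Missing
#' values are written as empty fields. Dot-prefixed latent columns are
#' dropped.
#'
#' @param cohort A subject-day tibble, e.g. from [simulate_cohort()].
#' @param path Output CSV path.
#' @param truth_path Optional YAML path for the ground-truth sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  out <- cohort[, !startsWith(names(cohort), "."), drop = FALSE]
  readr::write_csv(out, path, na = "")
  if (!is.null(truth_path)) {
    truth <- cohort_truth(cohort)
    if (is.null(truth)) abort("cohort carries no `truth` attribute")
    truth$subjects <- as.list(truth$subjects)
    yaml::write_yaml(truth, truth_path)
  }
  invisible(path)
}

#' Read a ground-truth YAML sidecar
#'
#' @param path Path written by [write_cohort()].
#' @return A list with `config`, `group_betas`, and `subjects` (as tibble).
#' @export
read_truth <- function(path) {
  truth <- yaml::read_yaml(path)
  truth$subjects <- tibble::as_tibble(truth$subjects)
  truth
}
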