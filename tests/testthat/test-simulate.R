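test_that("config validation names the offending field", {
  expect_error(sim_config(n_days = 0), "n_days")
  expect_error(sim_config(n_subjects_per_group = 0.5), "n_subjects_per_group")
  expect_error(sim_config(ar_mood = 1), "ar_mood")
  expect_error(sim_config(missing_prob = 1), "missing_prob")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(group_effects = list(bogus = list())), "group_effects")
  expect_error(sim_config(group_effects = list(anxious = list(zap = 1))), "zap")
})

test_that("group labels enforce the screening cutoffs", {
  expect_error(group_label("depressed", phq9 = 9, gad7 = 3), "imply")
  expect_error(group_label("control", phq9 = 12, gad7 = 3), "imply")
  expect_error(group_label("control", phq9 = -1, gad7 = 3), "phq9")
  g <- group_label("depressed_anxious", 14, 12)
  expect_identical(g$name, "depressed_anxious")
  expect_identical(group_from_scores(7, 11), "anxious")
  expect_error(reporting_style(scale = 0), "scale")
})

test_that("cohort has the configured shape and valid group scores", {
  cfg <- sim_config(n_subjects_per_group = 2, n_days = 10, seed = 1)
  cohort <- simulate_cohort(cfg)
  per <- dplyr::count(cohort, subject_id, group)
  expect_identical(nrow(per), 8L)                  # 4 groups x 2 subjects
  expect_true(all(per$n <= 10))
  expect_setequal(unique(per$group),
                  c("control", "depressed", "anxious", "depressed_anxious"))
  scores <- dplyr::distinct(cohort, subject_id, group, phq9, gad7)
  expect_true(all(scores$phq9[scores$group == "depressed"] >= 10))
  expect_true(all(scores$gad7[scores$group == "depressed"] < 10))
  expect_true(all(scores$phq9[scores$group == "anxious"] < 10))
  expect_true(all(scores$gad7[scores$group == "anxious"] >= 10))
  expect_true(all(scores$phq9[scores$group == "control"] < 10 &
                    scores$gad7[scores$group == "control"] < 10))
  expect_true(all(scores$phq9[scores$group == "depressed_anxious"] >= 10 &
                    scores$gad7[scores$group == "depressed_anxious"] >= 10))
})

test_that("all observed Likert values are integers in 0..8", {
  cohort <- simulate_cohort(sim_config(n_subjects_per_group = 4, n_days = 30,
                                       seed = 7, style_shift_sd = 2))
  lik <- c("sleep_quality", paste0("mood_", 1:3), paste0("stress_", 1:3),
           paste0("energy_", 1:3), paste0("focus_", 1:3))
  for (cl in lik) {
    v <- cohort[[cl]]
    expect_true(all(v >= 0 & v <= 8 & v == floor(v)), info = cl)
  }
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(n_subjects_per_group = 2, n_days = 15, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("degenerate noise-free subject reports the scale midpoint", {
  cfg <- sim_config(n_subjects_per_group = 1, n_days = 8, seed = 1,
                    beta_sleep_to_mood = 0, beta_mood_to_sleep = 0,
                    ar_mood = 0, ar_sleep = 0, confounder_strength = 0,
                    noise_sd = 0, report_sd = 0, missing_prob = 0)
  p <- simulate_subject(reporting_style(0, 1), group_label("control", 4, 3),
                        cfg, subject_seed = 5)
  expect_true(all(p$sleep_quality == 4))
  expect_true(all(p$mood_1 == 4 & p$mood_2 == 4 & p$mood_3 == 4))
})

test_that("null dynamics leave no lag-1 cross-correlation in the latents", {
  cfg <- sim_config(n_subjects_per_group = 1, n_days = 1500, seed = 3,
                    beta_sleep_to_mood = 0, beta_mood_to_sleep = 0,
                    confounder_strength = 0, missing_prob = 0)
  p <- simulate_subject(reporting_style(0, 1), group_label("control", 4, 3),
                        cfg, subject_seed = 11)
  n <- nrow(p)
  # mood on day t vs sleep reported morning t+1 (the coupled lag)
  r <- cor(p$.latent_mood[-n], p$.latent_sleep[-1])
  expect_lt(abs(r), 3 / sqrt(n - 1))
})

test_that("long-run regression on the latents recovers the cross-lag", {
  # OLS oracle on the latent series, averaged over subjects to tame MC error
  slopes <- vapply(1:5, function(s) {
    cfg <- sim_config(n_subjects_per_group = 1, n_days = 2000, seed = s,
                      beta_sleep_to_mood = 0.4, beta_mood_to_sleep = 0.13,
                      confounder_strength = 0, missing_prob = 0)
    p <- simulate_subject(reporting_style(0, 1), group_label("control", 4, 3),
                          cfg, subject_seed = s)
    unname(coef(lm(p$.latent_mood ~ p$.latent_sleep))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.4), 0.05)
})

test_that("missingness injection is MCAR with preserved day indices", {
  cfg <- sim_config(n_subjects_per_group = 1, n_days = 1000, seed = 2,
                    missing_prob = 0)
  p <- simulate_subject(reporting_style(0, 1), group_label("control", 4, 3),
                        cfg, subject_seed = 9)
  expect_identical(inject_missingness(p, 0, seed = 1), p)
  dropped <- inject_missingness(p, 0.5, seed = 1)
  # binomial 99% interval around 500 of 1000
  expect_gt(nrow(dropped), qbinom(0.005, 1000, 0.5))
  expect_lt(nrow(dropped), qbinom(0.995, 1000, 0.5))
  expect_true(all(dropped$day_index %in% p$day_index))
  expect_true(all(diff(dropped$day_index) >= 1))
  # retained rows are the original rows, indices untouched
  expect_identical(dropped, p[p$day_index %in% dropped$day_index, ])
  expect_error(inject_missingness(p, 1, seed = 1), "missing_prob")
})
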