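fake_effects <- function(effects, direction = "sleep_to_mood", T = 0,
                         group = "control", ids = NULL) {
  tibble::tibble(
    subject_id = ids %||% sprintf("S%03d", seq_along(effects)),
    group = group, direction = direction, T = T, matched = TRUE,
    effect = effects, n_treated_matched = 5L, n_control_matched = 5L,
    n_rows = 20L, excluded_reason = NA_character_)
}

test_that("bootstrap of identical effects is degenerate at their value", {
  bs <- bootstrap_mean_effect(fake_effects(rep(0.4, 12)), n_boot = 50, seed = 1)
  expect_equal(bs$mean_effect, 0.4)
  expect_equal(bs$sd_effect, 0)
  expect_true(bs$ci_lo <= bs$mean_effect & bs$mean_effect <= bs$ci_hi)
  expect_error(bootstrap_mean_effect(fake_effects(0.4), n_boot = 10, seed = 1),
               class = "sleepmood_precondition_error")
})

test_that("bootstrap SD tracks the CLT rate", {
  set.seed(8)
  eff <- fake_effects(rnorm(100, 0.3, 0.1))
  bs <- bootstrap_mean_effect(eff, n_boot = 200, seed = 2)
  expect_lt(bs$sd_effect, 0.01 * 1.5)
  expect_gt(bs$sd_effect, 0.01 / 1.5)
  expect_identical(bs, bootstrap_mean_effect(eff, n_boot = 200, seed = 2))
})

test_that("bootstrap intervals cover a known cohort mean at the right rate", {
  hits <- vapply(1:50, function(s) {
    eff <- withr::with_seed(s, fake_effects(rnorm(50, 0.3, 0.5)))
    bs <- bootstrap_mean_effect(eff, n_boot = 100, seed = s + 1000)
    bs$ci_lo <= 0.3 && 0.3 <= bs$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("identical direction arms give a null paired contrast", {
  eff <- fake_effects(c(0.1, 0.5, 0.3, 0.2, 0.4))
  cmp <- compare_directions_psm(eff, eff, n_boot = 100, seed = 3)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$paired)
})

test_that("disjoint subject sets fall back to unpaired with a warning", {
  a <- fake_effects(c(0.2, 0.3, 0.4), ids = c("A1", "A2", "A3"))
  b <- fake_effects(c(0.1, 0.2, 0.3), ids = c("B1", "B2", "B3"),
                    direction = "mood_to_sleep")
  expect_warning(cmp <- compare_directions_psm(a, b, n_boot = 100, seed = 4),
                 "unpaired")
  expect_false(cmp$paired)
})

test_that("group contrasts: self-identical groups differ by zero, empty groups skip", {
  eff <- dplyr::bind_rows(
    fake_effects(rep(0.4, 6), group = "control", ids = sprintf("C%d", 1:6)),
    fake_effects(rep(0.4, 6), group = "anxious", ids = sprintf("A%d", 1:6)),
    fake_effects(0.4, group = "depressed", ids = "D1"))
  gc <- group_contrasts(eff, n_boot = 100, seed = 5)
  anx <- gc[gc$group == "anxious", ]
  expect_equal(anx$difference, 0)
  expect_equal(anx$p_value, 1)
  dep <- gc[gc$group == "depressed", ]
  expect_true(dep$skipped)
  expect_true(is.na(dep$p_value))
  expect_error(group_contrasts(dplyr::filter(eff, group != "control"),
                               n_boot = 10, seed = 1),
               class = "sleepmood_precondition_error")
})

test_that("usable rows per subject never grow with history depth", {
  daily <- sim_daily(3, 20, seed = 41)
  counts <- sapply(0:3, function(T)
    nrow(build_lagged_dataset(daily, "sleep_to_mood", T)))
  expect_true(all(diff(counts) <= 0))
})

test_that("very short diaries sweep without crashing, exclusions reported", {
  daily <- sim_daily(2, 5, seed = 43, missing_prob = 0)
  sw <- run_T_sweep(daily, "mood_to_sleep", T_values = 0:3,
                    config = psm_config(seed = 2), n_boot = 20, seed = 3)
  expect_identical(nrow(sw$summaries), 5L)
  t3 <- sw$summaries[sw$summaries$arm == "T3", ]
  expect_true(is.na(t3$mean_effect) || t3$n_subjects < 3)
  expect_gt(sum(!is.na(sw$effects$excluded_reason)), 0)
})

test_that("sweep summaries carry matched and unmatched arms deterministically", {
  daily <- sim_daily(4, 30, seed = 45)
  sw1 <- run_T_sweep(daily, "sleep_to_mood", T_values = 0:1,
                     config = psm_config(seed = 9), n_boot = 40, seed = 6)
  sw2 <- run_T_sweep(daily, "sleep_to_mood", T_values = 0:1,
                     config = psm_config(seed = 9), n_boot = 40, seed = 6)
  expect_identical(sw1$summaries, sw2$summaries)
  expect_identical(sw1$summaries$arm, c("unmatched", "T0", "T1"))
})
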