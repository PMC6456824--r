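valid_effects <- function(effects) {
  effects |> dplyr::filter(is.na(.data$excluded_reason), is.finite(.data$effect))
}

#' Bootstrap the cohort mean personal effect over subjects
#'
#' Resamples subjects with replacement `n_boot` times, computes the mean
#' effect in each replicate, and reports the bootstrap mean, SD (the error
#' bar), and the 2.5/97.5 percentile interval.
#'
#' @param effects A per-subject effect tibble from [subject_effects()]
#'   (excluded subjects are ignored).
#' @param n_boot Number of replicates, default 100.
#' @param seed Integer seed.
#' @param group Label stored in the output (`"all"` by default).
#' @return One-row tibble: `direction`, `T`, `group`, `n_subjects`,
#'   `n_excluded`, `n_boot`, `mean_effect`, `sd_effect`, `ci_lo`, `ci_hi`,
#'   `seed`.
#' @export
bootstrap_mean_effect <- function(effects, n_boot = 100, seed = 1L,
                                  group = "all") {
  ok <- valid_effects(effects)
  if (nrow(ok) < 2L)
    abort("bootstrap needs at least 2 subjects with valid effects",
          class = "sleepmood_precondition_error")
  means <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(sample(ok$effect, nrow(ok), replace = TRUE)), numeric(1)))
  tibble::tibble(
    direction = if ("direction" %in% names(ok)) ok$direction[[1]] else NA_character_,
    T = if ("T" %in% names(ok)) ok$T[[1]] else NA_integer_,
    group = group,
    n_subjects = nrow(ok), n_excluded = nrow(effects) - nrow(ok),
    n_boot = n_boot,
    mean_effect = mean(means), sd_effect = stats::sd(means),
    ci_lo = unname(quantile(means, 0.025)),
    ci_hi = unname(quantile(means, 0.975)),
    seed = as.integer(seed)
  )
}

#' Bootstrap contrast of the two directions' matched effects
#'
#' Pairs each subject's effect in the two directions and bootstraps the mean
#' within-subject difference over subjects. When the two effect tables share
#' no subjects, falls back to an unpaired bootstrap and flags it.
#'
#' @param effects_a,effects_b Per-subject effect tibbles for the two
#'   directions (conventionally `a` = sleep_to_mood).
#' @param n_boot Number of replicates, default 100.
#' @param seed Integer seed.
#' @return One-row tibble: identifiers of both arms, observed `difference`,
#'   bootstrap SD and percentile interval, two-sided percentile `p_value`,
#'   and a `paired` flag.
#' @export
compare_directions_psm <- function(effects_a, effects_b, n_boot = 100,
                                   seed = 1L) {
  a <- valid_effects(effects_a); b <- valid_effects(effects_b)
  if (nrow(a) < 2L || nrow(b) < 2L)
    return(tibble::tibble(
      left = NA_character_, right = NA_character_, difference = NA_real_,
      boot_sd = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      p_value = NA_real_, paired = NA, n_boot = n_boot,
      n_subjects = nrow(a) + nrow(b)))
  common <- intersect(a$subject_id, b$subject_id)
  paired <- length(common) >= 2L
  if (!paired)
    rlang::warn("no common subjects between directions; using unpaired bootstrap")
  diffs <- with_seed(seed, {
    if (paired) {
      d <- a$effect[match(common, a$subject_id)] -
        b$effect[match(common, b$subject_id)]
      vapply(seq_len(n_boot), function(i)
        mean(sample(d, length(d), replace = TRUE)), numeric(1))
    } else {
      vapply(seq_len(n_boot), function(i)
        mean(sample(a$effect, nrow(a), replace = TRUE)) -
          mean(sample(b$effect, nrow(b), replace = TRUE)), numeric(1))
    }
  })
  obs <- if (paired)
    mean(a$effect[match(common, a$subject_id)] -
           b$effect[match(common, b$subject_id)])
  else mean(a$effect) - mean(b$effect)
  tibble::tibble(
    left = paste0(a$direction[[1]], "/T", a$T[[1]]),
    right = paste0(b$direction[[1]], "/T", b$T[[1]]),
    difference = obs, boot_sd = stats::sd(diffs),
    ci_lo = unname(quantile(diffs, 0.025)),
    ci_hi = unname(quantile(diffs, 0.975)),
    p_value = percentile_p(diffs),
    paired = paired, n_boot = n_boot,
    n_subjects = if (paired) length(common) else nrow(a) + nrow(b)
  )
}

#' Symptom-group contrasts of the mean personal effect
#'
#' For each non-control group with at least two valid subjects, bootstraps
#' (unpaired, since groups contain different subjects) the difference in
#' mean personal effect against the control group.
#'
#' @param effects A per-subject effect tibble carrying a `group` column.
#' @param n_boot Number of replicates, default 100.
#' @param seed Integer seed.
#' @return Tibble with one row per contrast: `direction`, `T`, `group`,
#'   `difference` (group minus control), bootstrap SD, percentile interval,
#'   two-sided percentile `p_value`, counts, and a `skipped` flag for groups
#'   with too few valid subjects.
#' @export
group_contrasts <- function(effects, n_boot = 100, seed = 1L) {
  ok <- valid_effects(effects)
  ctrl <- ok |> dplyr::filter(.data$group == "control")
  if (nrow(ctrl) < 2L)
    abort("group contrasts need >= 2 valid control subjects",
          class = "sleepmood_precondition_error")
  purrr::map_dfr(setdiff(.group_names, "control"), function(g) {
    gg <- ok |> dplyr::filter(.data$group == g)
    base <- tibble::tibble(
      direction = ok$direction[[1]], T = ok$T[[1]], group = g,
      n_group = nrow(gg), n_control = nrow(ctrl))
    if (nrow(gg) < 2L)
      return(dplyr::mutate(base, difference = NA_real_, boot_sd = NA_real_,
                           ci_lo = NA_real_, ci_hi = NA_real_,
                           p_value = NA_real_, skipped = TRUE))
    diffs <- with_seed(derive_seed(seed, sum(utf8ToInt(g))), {
      vapply(seq_len(n_boot), function(i)
        mean(sample(gg$effect, nrow(gg), replace = TRUE)) -
          mean(sample(ctrl$effect, nrow(ctrl), replace = TRUE)), numeric(1))
    })
    dplyr::mutate(base,
                  difference = mean(gg$effect) - mean(ctrl$effect),
                  boot_sd = stats::sd(diffs),
                  ci_lo = unname(quantile(diffs, 0.025)),
                  ci_hi = unname(quantile(diffs, 0.975)),
                  p_value = percentile_p(diffs), skipped = FALSE)
  })
}

#' Unmatched-plus-matched history-depth sweep
#'
#' The full bar-chart procedure for one direction: the unmatched effect over
#' all paired days, then the matched effect at each history depth in
#' `T_values`, each summarized by a subject-level bootstrap. Row counts per
#' subject shrink as `T` grows; exclusions are reported per arm.
#'
#' @param daily A daily panel tibble.
#' @param direction `"sleep_to_mood"` or `"mood_to_sleep"`.
#' @param T_values History depths to sweep, default `0:3`.
#' @param config A [psm_config()] (its `T` is overridden per arm).
#' @param n_boot Bootstrap replicates per arm, default 100.
#' @param seed Integer seed.
#' @return List with `summaries` (one row per arm: `arm` is `"unmatched"` or
#'   `"T0"`..`"T3"`) and `effects` (stacked per-subject tables).
#' @export
run_T_sweep <- function(daily, direction, T_values = 0:3,
                        config = psm_config(), n_boot = 100, seed = 1L) {
  direction <- match_direction(direction)
  arms <- list()
  effects_all <- list()
  # an arm where fewer than 2 subjects survive the gates is reported as an
  # all-NA summary, not an error (e.g. T = 3 on very short diaries)
  safe_boot <- function(eff, arm, boot_seed) {
    tryCatch(
      bootstrap_mean_effect(eff, n_boot = n_boot, seed = boot_seed),
      sleepmood_precondition_error = function(e) tibble::tibble(
        direction = direction, T = eff$T[seq_len(min(1, nrow(eff)))][1],
        group = "all", n_subjects = nrow(valid_effects(eff)),
        n_excluded = nrow(eff) - nrow(valid_effects(eff)),
        n_boot = n_boot, mean_effect = NA_real_, sd_effect = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, seed = as.integer(boot_seed))
    ) |> dplyr::mutate(arm = arm, .before = 1)
  }
  unm <- subject_effects(daily, direction, config, matched = FALSE)
  effects_all$unmatched <- dplyr::mutate(unm, arm = "unmatched")
  arms$unmatched <- safe_boot(unm, "unmatched", derive_seed(seed, 1000L))
  for (tt in T_values) {
    cfg <- config; cfg$T <- tt
    eff <- subject_effects(daily, direction, cfg, matched = TRUE)
    nm <- paste0("T", tt)
    effects_all[[nm]] <- dplyr::mutate(eff, arm = nm)
    arms[[nm]] <- safe_boot(eff, nm, derive_seed(seed, 1000L + tt + 1L))
  }
  list(summaries = dplyr::bind_rows(arms),
       effects = dplyr::bind_rows(effects_all))
}
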