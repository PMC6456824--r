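#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes the panel CSV, the ground-truth YAML
#' sidecar, and a run manifest into `outdir`. Identical config + seed
#' reproduces every file byte-identically.
#'
#' @param config A [sim_config()], or a path to a YAML file whose keys are
#'   `sim_config()` arguments.
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with the written paths and the realized cohort
#'   summary (subjects, mean days per subject, realized missingness).
#' @export
run_simulate <- function(config, outdir) {
  if (is.character(config)) config <- sim_config_from_yaml(config)
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  paths <- list(cohort = file.path(outdir, "cohort.csv"),
                truth = file.path(outdir, "truth.yaml"),
                manifest = file.path(outdir, "manifest.json"))
  write_cohort(cohort, paths$cohort, truth_path = paths$truth)
  n_subj <- dplyr::n_distinct(cohort$subject_id)
  summary <- list(
    n_subjects = n_subj,
    n_days_planned = config$n_days,
    mean_days_observed = nrow(cohort) / n_subj,
    realized_missingness = 1 - nrow(cohort) / (n_subj * config$n_days)
  )
  write_manifest(paths$manifest, stage = "simulate",
                 config = unclass(config)[!vapply(config, is.null, TRUE)],
                 seed = config$seed, inputs = character(), summary = summary)
  rlang::inform(sprintf(
    "simulated %d subjects, %.1f observed days each (%.1f%% missing)",
    summary$n_subjects, summary$mean_days_observed,
    100 * summary$realized_missingness))
  invisible(list(paths = paths, summary = summary, cohort = cohort))
}

sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(sprintf("unknown config key `%s` in %s", bad[[1]], path),
          class = "sleepmood_config_error")
  do.call(sim_config, raw)
}

#' Run the full day-level causal analysis on a panel CSV
#'
#' Executes the whole pipeline on a long-format daily panel: read and
#' aggregate; mixed-effects cross-effect fits on raw and within-person
#' normalized scores for both directions, with a bootstrap direction
#' comparison on the normalized arm; the unmatched-plus-matched
#' history-depth sweep per direction with per-arm direction contrasts;
#' covariate balance; and symptom-group contrasts (at `T = 1`, where the
#' previous day's mood and sleep also enter the confounder set). Writes
#' `results.json`, `effects.csv`, `balance.csv`, figures, and a manifest.
#'
#' @param input Path to a panel CSV in the schema of [write_cohort()].
#' @param outdir Output directory, created if absent.
#' @param directions Directions to analyze (default both).
#' @param T_values History depths for the sweep, default `0:3`.
#' @param n_boot Bootstrap replicates, default 100.
#' @param seed Master seed; fanned out deterministically to every stage.
#' @param psm A [psm_config()] supplying matching parameters.
#' @param truth Optional path to a ground-truth YAML from [run_simulate()];
#'   when given, recovery diagnostics (estimate minus truth) are appended.
#' @param group_T History depth for the group contrasts, default 1.
#' @param write_figures Write the bar-chart figures (default `TRUE`).
#' @return Invisibly, the results list (also serialized as JSON).
#' @export
run_analysis <- function(input, outdir,
                         directions = c("sleep_to_mood", "mood_to_sleep"),
                         T_values = 0:3, n_boot = 100, seed = 1L,
                         psm = psm_config(), truth = NULL, group_T = 1,
                         write_figures = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  directions <- vapply(directions, match_direction, character(1))
  daily <- read_panel_csv(input)
  psm$seed <- derive_seed(seed, 7L)

  datasets <- lapply(setNames(directions, directions), function(dd)
    build_lagged_dataset(daily, dd, T = 0))
  zdaily <- znormalize_within_subject(daily, c("sleep_quality", "mood"))
  zdatasets <- lapply(setNames(directions, directions), function(dd)
    build_lagged_dataset(zdaily, dd, T = 0))

  fits <- list()
  for (dd in directions) {
    fits[[paste0(dd, "_raw")]] <- fit_raw(datasets[[dd]])
    fits[[paste0(dd, "_normalized")]] <- fit_normalized(zdatasets[[dd]])
  }
  model_tbl <- dplyr::bind_rows(lapply(fits, glance.crosslag_fit))

  mm_contrast <- NULL
  if (all(.directions %in% directions)) {
    mm_contrast <- compare_directions(
      fits[["sleep_to_mood_normalized"]], fits[["mood_to_sleep_normalized"]],
      n_boot = n_boot, seed = derive_seed(seed, 11L))
  }

  sweeps <- list(); sweep_effects <- list()
  for (dd in directions) {
    sw <- run_T_sweep(daily, dd, T_values = T_values, config = psm,
                      n_boot = n_boot, seed = derive_seed(seed, 13L))
    sweeps[[dd]] <- sw$summaries
    sweep_effects[[dd]] <- sw$effects
  }
  sweep_tbl <- dplyr::bind_rows(sweeps)
  effects_tbl <- dplyr::bind_rows(sweep_effects)

  psm_contrasts <- NULL
  if (all(.directions %in% directions)) {
    psm_contrasts <- purrr::map_dfr(unique(effects_tbl$arm), function(a) {
      ea <- effects_tbl |> dplyr::filter(.data$arm == a,
                                         .data$direction == "sleep_to_mood")
      eb <- effects_tbl |> dplyr::filter(.data$arm == a,
                                         .data$direction == "mood_to_sleep")
      compare_directions_psm(ea, eb, n_boot = n_boot,
                             seed = derive_seed(seed, 17L)) |>
        dplyr::mutate(arm = a, .before = 1)
    })
  }

  balance <- lapply(setNames(directions, directions), function(dd)
    cohort_balance(daily, dd, config = psm))
  balance_tbl <- dplyr::bind_rows(
    lapply(names(balance), function(dd)
      dplyr::mutate(balance[[dd]]$summary, direction = dd, .before = 1)))

  contrasts_tbl <- NULL
  gcfg <- psm; gcfg$T <- group_T
  contrasts_tbl <- purrr::map_dfr(directions, function(dd) {
    eff <- subject_effects(daily, dd, gcfg, matched = TRUE)
    tryCatch(
      group_contrasts(eff, n_boot = n_boot, seed = derive_seed(seed, 19L)),
      sleepmood_precondition_error = function(e) tibble::tibble())
  })

  exclusions <- effects_tbl |>
    dplyr::filter(!is.na(.data$excluded_reason)) |>
    dplyr::count(.data$direction, .data$arm, .data$excluded_reason)

  results <- list(
    version = as.character(packageVersion("sleepmood")),
    seed = as.integer(seed), n_boot = n_boot,
    input = basename(input),
    models = model_tbl,
    model_direction_contrast = if (!is.null(mm_contrast))
      unclass(mm_contrast)[c("difference", "p_value", "boot_sd", "ci",
                             "n_boot")] else NULL,
    psm_summaries = sweep_tbl,
    psm_direction_contrasts = psm_contrasts,
    group_contrasts = contrasts_tbl,
    balance = balance_tbl,
    exclusions = exclusions
  )

  if (!is.null(truth)) {
    tr <- read_truth(truth)
    norm_rows <- model_tbl |> dplyr::filter(.data$normalized)
    results$recovery <- tibble::tibble(
      direction = norm_rows$direction,
      truth = vapply(norm_rows$direction, function(dd)
        if (dd == "sleep_to_mood") tr$config$beta_sleep_to_mood else
          tr$config$beta_mood_to_sleep, numeric(1)),
      estimate = norm_rows$b1
    ) |> dplyr::mutate(error = .data$estimate - .data$truth)
  }

  paths <- list(results = file.path(outdir, "results.json"),
                effects = file.path(outdir, "effects.csv"),
                balance = file.path(outdir, "balance.csv"),
                manifest = file.path(outdir, "manifest.json"))
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  readr::write_csv(effects_tbl, paths$effects, na = "")
  readr::write_csv(balance_tbl, paths$balance, na = "")
  if (write_figures) {
    try({
      p1 <- plot_effect_sweep(sweep_tbl)
      ggplot2::ggsave(file.path(outdir, "effect_sweep.png"), p1,
                      width = 7, height = 4.5, dpi = 150)
      if (!is.null(contrasts_tbl) && nrow(contrasts_tbl)) {
        p2 <- plot_group_effects(effects_tbl |>
                                   dplyr::filter(.data$arm == paste0("T", group_T)))
        ggplot2::ggsave(file.path(outdir, "group_effects.png"), p2,
                        width = 7, height = 4.5, dpi = 150)
      }
    }, silent = TRUE)
  }
  write_manifest(paths$manifest, stage = "analyze",
                 config = list(directions = directions, T_values = T_values,
                               n_boot = n_boot, group_T = group_T,
                               psm = unclass(psm)[!vapply(psm, is.null, TRUE)]),
                 seed = seed, inputs = unname(tools::md5sum(input)),
                 summary = list(n_subjects = dplyr::n_distinct(daily$subject_id),
                                n_rows = nrow(daily)))
  for (dd in directions) {
    exc <- exclusions |> dplyr::filter(.data$direction == dd)
    rlang::inform(sprintf("%s: %d subject-arm exclusions across gates",
                          dd, sum(exc$n)))
  }
  invisible(results)
}

write_manifest <- function(path, stage, config, seed, inputs, summary) {
  jsonlite::write_json(list(
    stage = stage, package = "sleepmood",
    version = as.character(packageVersion("sleepmood")),
    seed = as.integer(seed), config = config,
    input_md5 = inputs, summary = summary
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a human-readable summary of an analysis results file
#'
#' @param results_path Path to a `results.json` written by [run_analysis()].
#' @return The report text, invisibly; also printed to the console.
#' @export
render_report <- function(results_path) {
  res <- tryCatch(jsonlite::read_json(results_path, simplifyVector = TRUE),
                  error = function(e)
                    abort(sprintf("malformed results JSON in `%s`: %s",
                                  results_path, conditionMessage(e))))
  if (is.null(res$version))
    abort(sprintf("`%s` is not a sleepmood results file (no version field)",
                  results_path))
  lines <- c(
    sprintf("sleepmood analysis report (package %s, seed %s)", res$version, res$seed),
    "", "== Mixed-effects cross-effects ==",
    utils::capture.output(print.data.frame(
      as.data.frame(res$models), digits = 3, row.names = FALSE)))
  if (!is.null(res$model_direction_contrast))
    lines <- c(lines, sprintf(
      "normalized direction difference (sleep_to_mood - mood_to_sleep): %.3f, p = %.3g",
      res$model_direction_contrast$difference,
      res$model_direction_contrast$p_value))
  lines <- c(lines, "", "== Personal causal effects (bootstrap over subjects) ==",
             utils::capture.output(print.data.frame(
               as.data.frame(res$psm_summaries), digits = 3, row.names = FALSE)))
  lines <- c(lines, "", "== Group contrasts vs control ==",
             if (!is.null(res$group_contrasts) && length(res$group_contrasts) &&
                 nrow(as.data.frame(res$group_contrasts)))
               utils::capture.output(print.data.frame(
                 as.data.frame(res$group_contrasts), digits = 3,
                 row.names = FALSE)) else "none")
  lines <- c(lines, "", "== Exclusions ==",
             if (!is.null(res$exclusions) && length(res$exclusions) &&
                 nrow(as.data.frame(res$exclusions)))
               utils::capture.output(print.data.frame(
                 as.data.frame(res$exclusions), row.names = FALSE)) else "none")
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
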