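#' Mixed-effects estimate of the population cross-effect (raw scores)
#'
#' Fits `outcome ~ treatment` with a per-subject random intercept and random
#' slope by REML and reports the fixed slope, its standard error, and a
#' large-sample normal p-value. On non-convergence the random-effects
#' structure is simplified along a standard ladder (correlated intercept +
#' slope, then uncorrelated, then intercept only); if every rung fails the
#' fit is returned with `converged = FALSE` and the optimizer diagnostics.
#'
#' @param dataset A lagged day-pair tibble from [build_lagged_dataset()].
#' @param random `"slope_intercept"` (default) or `"intercept"` for a
#'   random-intercept-only model.
#' @return A `crosslag_fit` object; see [tidy.crosslag_fit()].
#' @export
fit_raw <- function(dataset, random = c("slope_intercept", "intercept")) {
  random <- match.arg(random)
  forms <- if (random == "slope_intercept") c(
    "outcome ~ treatment + (1 + treatment | subject_id)",
    "outcome ~ treatment + (1 + treatment || subject_id)",
    "outcome ~ treatment + (1 | subject_id)"
  ) else "outcome ~ treatment + (1 | subject_id)"
  fit_crosslag(dataset, forms, normalized = FALSE)
}

#' Mixed-effects estimate on within-person normalized scores
#'
#' For z-normalized data every subject has mean 0 and SD 1 in both variables,
#' so the model drops the intercept entirely: a fixed slope constrained
#' through the origin with a per-subject random slope,
#' `outcome ~ 0 + treatment + (0 + treatment | subject_id)`.
#'
#' @param dataset A lagged day-pair tibble whose `treatment` and `outcome`
#'   are already z-normalized per subject (see
#'   [znormalize_within_subject()]).
#' @return A `crosslag_fit` object.
#' @export
fit_normalized <- function(dataset) {
  fit_crosslag(dataset,
               "outcome ~ 0 + treatment + (0 + treatment | subject_id)",
               normalized = TRUE)
}

fit_crosslag <- function(dataset, formulas, normalized) {
  stopifnot(all(c("subject_id", "treatment", "outcome") %in% names(dataset)))
  d <- dataset |>
    dplyr::filter(!is.na(.data$treatment), !is.na(.data$outcome))
  counts <- table(d$subject_id)
  few <- names(counts)[counts < 2L]
  if (length(few)) {
    rlang::inform(sprintf(
      "dropping %d subject(s) with fewer than 2 usable rows", length(few)))
    d <- d[!d$subject_id %in% few, , drop = FALSE]
  }
  if (dplyr::n_distinct(d$subject_id) < 2L)
    abort("mixed-effects fit needs at least 2 subjects with >= 2 rows each",
          class = "sleepmood_precondition_error")
  d$subject_id <- factor(d$subject_id)

  model <- NULL; used <- NA_character_; msgs <- character()
  for (f in formulas) {
    attempt_msgs <- character()
    res <- tryCatch(
      withCallingHandlers(
        lme4::lmer(stats::as.formula(f), data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")),
        warning = function(w) {
          attempt_msgs <<- c(attempt_msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        attempt_msgs <<- c(attempt_msgs, conditionMessage(e)); NULL
      })
    msgs <- c(msgs, attempt_msgs)
    if (!is.null(res)) {
      model <- res; used <- f
      clean <- !any(grepl("failed to converge", attempt_msgs))
      if (clean) break
      msgs <- c(msgs, sprintf("simplifying random effects after `%s`", f))
    }
  }
  if (is.null(model)) {
    return(structure(list(
      direction = attr(dataset, "direction"), normalized = normalized,
      b1 = NA_real_, se = NA_real_, p_value = NA_real_,
      n_subjects = dplyr::n_distinct(d$subject_id), n_rows = nrow(d),
      random_effect_variances = NULL, converged = FALSE,
      formula = NA_character_, messages = msgs, model = NULL, data = d
    ), class = "crosslag_fit"))
  }
  b1 <- unname(lme4::fixef(model)["treatment"])
  # vcov can fail on degenerate fits (zero residual variance); the slope is
  # still well-defined there
  se <- tryCatch(
    unname(sqrt(diag(as.matrix(vcov(model)))[
      names(lme4::fixef(model)) == "treatment"])),
    error = function(e) NA_real_, warning = function(w) NA_real_)
  if (length(se) != 1L || !is.finite(se)) se <- NA_real_
  vc <- as.data.frame(lme4::VarCorr(model))
  revar <- setNames(vc$vcov, paste(vc$grp, vc$var1, vc$var2, sep = "."))
  structure(list(
    direction = attr(dataset, "direction"), normalized = normalized,
    b1 = b1, se = se, p_value = 2 * pnorm(-abs(b1 / se)),
    n_subjects = nlevels(d$subject_id), n_rows = nrow(d),
    random_effect_variances = revar,
    converged = TRUE, formula = used, messages = msgs,
    model = model, data = d
  ), class = "crosslag_fit")
}

#' @export
print.crosslag_fit <- function(x, ...) {
  cat(sprintf(
    "<crosslag_fit> %s (%s scores)\n  b1 = %.4f (SE %.4f), p = %.3g\n  %d subjects, %d rows%s\n",
    x$direction %||% "?", if (x$normalized) "normalized" else "raw",
    x$b1, x$se, x$p_value, x$n_subjects, x$n_rows,
    if (!x$converged) "  [DID NOT CONVERGE]" else ""))
  invisible(x)
}

#' Tidy a cross-lag mixed-model fit
#'
#' @param x A `crosslag_fit`.
#' @param ... Unused.
#' @return One-row tibble with the slope estimate, standard error, and
#'   p-value (broom convention).
#' @export
tidy.crosslag_fit <- function(x, ...) {
  tibble::tibble(
    term = "treatment", estimate = x$b1, std.error = x$se,
    statistic = x$b1 / x$se, p.value = x$p_value
  )
}

#' @rdname tidy.crosslag_fit
#' @export
glance.crosslag_fit <- function(x, ...) {
  tibble::tibble(
    direction = x$direction %||% NA_character_, normalized = x$normalized,
    b1 = x$b1, se = x$se, p_value = x$p_value,
    n_subjects = x$n_subjects, n_rows = x$n_rows, converged = x$converged
  )
}

# fast bootstrap refit: resample subjects, reuse warm-start theta
refit_resampled <- function(fit, idx_by_subject, ids, theta, ctrl) {
  rows <- unlist(idx_by_subject[ids], use.names = FALSE)
  bd <- fit$data[rows, , drop = FALSE]
  bd$subject_id <- factor(rep.int(seq_along(ids), lengths(idx_by_subject[ids])))
  tryCatch({
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(fit$formula), data = bd, REML = TRUE,
                 control = ctrl, start = theta)))
    unname(lme4::fixef(m)["treatment"])
  }, error = function(e) NA_real_)
}

#' Bootstrap comparison of the two cross-effect directions
#'
#' Resamples subjects with replacement; in each replicate both directional
#' models are refitted on the resampled cohort and the difference in fixed
#' slopes `b1(a) - b1(b)` recorded. The p-value is the two-sided percentile
#' bootstrap p for that difference against zero.
#'
#' @param fit_a,fit_b `crosslag_fit` objects from the same cohort and the
#'   same normalization arm (conventionally `a` = sleep_to_mood).
#' @param n_boot Number of bootstrap replicates (default 100). Fewer than 50
#'   is allowed but recorded as a warning in the result.
#' @param seed Integer seed.
#' @return A `crosslag_contrast` list: observed `difference`, `p_value`,
#'   bootstrap mean/SD, percentile interval, replicate count.
#' @export
compare_directions <- function(fit_a, fit_b, n_boot = 100, seed = 1L) {
  stopifnot(inherits(fit_a, "crosslag_fit"), inherits(fit_b, "crosslag_fit"))
  if (isTRUE(fit_a$normalized) != isTRUE(fit_b$normalized))
    abort("fits must come from the same normalization arm")
  warnings <- character()
  if (n_boot < 50)
    warnings <- c(warnings, sprintf("n_boot = %d is below 50; the percentile p-value is coarse", n_boot))
  subjects <- union(levels(fit_a$data$subject_id), levels(fit_b$data$subject_id))
  idx_a <- split(seq_len(nrow(fit_a$data)), fit_a$data$subject_id)
  idx_b <- split(seq_len(nrow(fit_b$data)), fit_b$data$subject_id)
  th_a <- if (!is.null(fit_a$model)) lme4::getME(fit_a$model, "theta") else NULL
  th_b <- if (!is.null(fit_b$model)) lme4::getME(fit_b$model, "theta") else NULL
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ids <- sample(subjects, length(subjects), replace = TRUE)
      ba <- refit_resampled(fit_a, idx_a, intersect_ids(ids, idx_a), th_a, ctrl)
      bb <- refit_resampled(fit_b, idx_b, intersect_ids(ids, idx_b), th_b, ctrl)
      ba - bb
    }, numeric(1))
  })
  ok <- diffs[is.finite(diffs)]
  structure(list(
    difference = fit_a$b1 - fit_b$b1,
    p_value = percentile_p(ok),
    boot_mean = mean(ok), boot_sd = stats::sd(ok),
    ci = unname(quantile(ok, c(0.025, 0.975))),
    n_boot = n_boot, n_failed = n_boot - length(ok),
    warnings = warnings
  ), class = "crosslag_contrast")
}

intersect_ids <- function(ids, idx) ids[ids %in% names(idx)]

#' @export
print.crosslag_contrast <- function(x, ...) {
  cat(sprintf(
    "<crosslag_contrast> difference = %.4f, p = %.3g (bootstrap SD %.4f, %d reps)\n",
    x$difference, x$p_value, x$boot_sd, x$n_boot))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
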