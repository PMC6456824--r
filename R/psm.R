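#' Matching configuration for the per-subject PSM analysis
#'
#' @param T History depth 0-3 (how many previous days of mood and sleep
#'   enter the confounder vector).
#' @param caliper Maximum allowed matching distance, as a multiple of the SD
#'   of the logit propensity (the applied literature's common default, 0.2),
#'   or `NULL` for no caliper. The caliper is what trims off-support days
#'   and so carries the confounding correction, but on per-subject series of
#'   a few dozen days it discards many candidate pairs and inflates the
#'   variance of the per-subject effect; `NULL` keeps every possible pair
#'   (maximal precision, no trimming). See the methods vignette for the
#'   measured trade-off.
#' @param caliper_scale `"sd_logit"` (caliper is a multiple of the logit-SD)
#'   or `"logit"` (caliper is an absolute logit distance).
#' @param with_replacement Reuse controls across pairs. Default `FALSE`.
#' @param tie_rule Days exactly at the subject mean: `"strict_greater"`
#'   (default; ties are controls) or `"greater_equal"` (ties are treated).
#' @param ridge L2 penalty on the standardized propensity coefficients
#'   (intercept unpenalized); guarantees a finite fit under separation on
#'   short per-subject series. Default 1 (a unit-information-style prior).
#' @param variance_threshold Treatment-variance exclusion threshold
#'   (strict `<`). Default 0.5.
#' @param seed Integer seed controlling the shuffled matching order.
#' @return A list of class `psm_config`.
#' @export
psm_config <- function(T = 0, caliper = 0.2, caliper_scale = c("sd_logit", "logit"),
                       with_replacement = FALSE,
                       tie_rule = c("strict_greater", "greater_equal"),
                       ridge = 1, variance_threshold = 0.5, seed = 1L) {
  if (!T %in% 0:3) stop_field("T", "history depth must be one of 0, 1, 2, 3")
  if (!is.null(caliper) && (!is.numeric(caliper) || caliper <= 0))
    stop_field("caliper", "must be a positive number or NULL")
  if (!is.numeric(ridge) || ridge < 0)
    stop_field("ridge", "must be a non-negative number")
  structure(list(
    T = T, caliper = caliper, caliper_scale = match.arg(caliper_scale),
    with_replacement = isTRUE(with_replacement),
    tie_rule = match.arg(tie_rule), ridge = ridge,
    variance_threshold = variance_threshold, seed = seed
  ), class = "psm_config")
}

#' Binarize a treatment series at the subject mean
#'
#' Days above the subject's own mean become treated (1), days below become
#' controls (0). Under the default rule a day exactly at the mean is a
#' control (strict `>`); the statistic is therefore invariant to positive
#' affine rescaling of the series.
#'
#' @param values Numeric per-subject treatment series.
#' @param tie_rule `"strict_greater"` (default) or `"greater_equal"`.
#' @return Integer 0/1 vector.
#' @examples
#' binarize_treatment(c(3, 5, 7)) # mean 5 -> 0, 0, 1
#' @export
binarize_treatment <- function(values, tie_rule = c("strict_greater",
                                                    "greater_equal")) {
  tie_rule <- match.arg(tie_rule)
  m <- mean(values)
  if (tie_rule == "strict_greater") as.integer(values > m) else
    as.integer(values >= m)
}

# design matrix for the per-subject propensity model: numeric confounders
# plus one-hot codes (first level dropped) for day of week and day type,
# standardized within subject; zero-variance columns are dropped
propensity_design <- function(rows) {
  num <- as.matrix(rows[, intersect(.confounder_num, names(rows)), drop = FALSE])
  lag_cols <- grep("^(mood|sleep)_lag[0-9]+$", names(rows), value = TRUE)
  if (length(lag_cols))
    num <- cbind(num, as.matrix(rows[, lag_cols, drop = FALSE]))
  cat_mats <- lapply(intersect(.confounder_cat, names(rows)), function(v) {
    f <- factor(rows[[v]])
    if (nlevels(f) < 2L) return(NULL)
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(v, levels(f)[-1])
    m
  })
  X <- do.call(cbind, c(list(num), Filter(Negate(is.null), cat_mats)))
  if (is.null(X) || !ncol(X)) return(NULL)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (!ncol(X)) return(NULL)
  scale(X)
}

#' Ridge-penalized logistic propensity scores
#'
#' Estimates, within one subject, the probability that a day is a treated
#' day given its confounder vector, by Newton iteration on the L2-penalized
#' logistic log-likelihood (intercept unpenalized, confounders standardized
#' within subject). The penalty keeps the fit finite under perfect
#' separation, which is common on series of a few dozen days.
#'
#' @param rows One subject's lagged day rows (see [build_lagged_dataset()]).
#' @param treatment Integer 0/1 vector, from [binarize_treatment()].
#' @param ridge Penalty strength. Default 1.
#' @return List with `scores` (probabilities strictly inside (0,1)) and
#'   `coef` (named coefficients on the standardized scale). With no varying
#'   confounders the model is intercept-only and every score equals the
#'   treated fraction.
#' @export
estimate_propensity <- function(rows, treatment, ridge = 1) {
  stopifnot(length(treatment) == nrow(rows), all(treatment %in% 0:1))
  X <- propensity_design(rows)
  n <- length(treatment)
  if (is.null(X)) {
    p <- rep(mean(treatment), n)
    return(list(scores = pmin(1 - 1e-8, pmax(1e-8, p)),
                coef = c(`(Intercept)` = qlogis(mean(treatment)))))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(ridge, ncol(X)))
  beta <- rep(0, ncol(Xd))
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, treatment - mu)) - pen * beta
    H <- crossprod(Xd * w, Xd) + diag(pen, ncol(Xd))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  scores <- plogis(drop(Xd %*% beta))
  list(scores = pmin(1 - 1e-8, pmax(1e-8, scores)),
       coef = setNames(beta, colnames(Xd)))
}

#' Greedy 1:1 nearest-neighbor matching on the propensity score
#'
#' Treated days are processed in an order shuffled by `seed`; each is paired
#' with the nearest remaining control on the logit-propensity scale, subject
#' to the caliper. Unmatched days are discarded.
#'
#' @param scores Propensity scores in (0, 1).
#' @param treatment Integer 0/1 vector.
#' @param config A [psm_config()] (supplies caliper, replacement, seed).
#' @return Tibble of matched index pairs (`treated`, `control`, `distance`);
#'   zero rows when no pair can be formed.
#' @export
match_pairs <- function(scores, treatment, config = psm_config()) {
  stopifnot(length(scores) == length(treatment))
  lg <- qlogis(pmin(1 - 1e-8, pmax(1e-8, scores)))
  t_idx <- which(treatment == 1L)
  c_idx <- which(treatment == 0L)
  if (!length(t_idx) || !length(c_idx))
    return(tibble::tibble(treated = integer(), control = integer(),
                          distance = double()))
  cal <- if (is.null(config$caliper)) Inf else if
    (config$caliper_scale == "logit") config$caliper else {
      s <- stats::sd(lg)
      if (is.na(s) || s == 0) Inf else config$caliper * s
    }
  # sample(x) on a length-1 vector would permute seq_len(x)
  order_t <- if (length(t_idx) == 1L) t_idx else
    with_seed(config$seed %||% 1L, sample(t_idx))
  available <- rep(TRUE, length(c_idx))
  out <- vector("list", length(order_t)); k <- 0L
  for (ti in order_t) {
    cand <- if (config$with_replacement) seq_along(c_idx) else which(available)
    if (!length(cand)) break
    dist <- abs(lg[c_idx[cand]] - lg[ti])
    j <- cand[which.min(dist)]
    if (min(dist) <= cal) {
      k <- k + 1L
      out[[k]] <- c(ti, c_idx[j], min(dist))
      if (!config$with_replacement) available[j] <- FALSE
    }
  }
  if (!k) return(tibble::tibble(treated = integer(), control = integer(),
                                distance = double()))
  m <- do.call(rbind, out[seq_len(k)])
  tibble::tibble(treated = as.integer(m[, 1]), control = as.integer(m[, 2]),
                 distance = m[, 3])
}

effect_row <- function(effect = NA_real_, n1 = NA_integer_, n0 = NA_integer_,
                       reason = NA_character_) {
  tibble::tibble(effect = effect, n_treated_matched = n1,
                 n_control_matched = n0, excluded_reason = reason)
}

#' Personal causal effect from matched day pairs
#'
#' The standardized mean difference in outcome between the matched treated
#' and matched control days: difference of group means divided by the pooled
#' (df-weighted) SD of the two matched groups — a Cohen's-d-type statistic,
#' invariant to positive affine rescaling of the outcome.
#'
#' @param outcome Outcome vector for all the subject's rows.
#' @param pairs Matched pairs from [match_pairs()].
#' @return One-row tibble: `effect`, `n_treated_matched`,
#'   `n_control_matched`, `excluded_reason` (`"no_match"` when no pairs,
#'   `"degenerate_outcome"` when the pooled SD is 0).
#' @examples
#' # treated (5, 7) vs control (3, 5): (6 - 4) / sqrt(2)
#' @export
personal_effect <- function(outcome, pairs) {
  if (!nrow(pairs)) return(effect_row(reason = "no_match"))
  y1 <- outcome[pairs$treated]
  y0 <- outcome[pairs$control]
  s <- pooled_sd(y1, y0)
  if (!is.finite(s) || s == 0)
    return(effect_row(n1 = length(y1), n0 = length(y0),
                      reason = "degenerate_outcome"))
  effect_row((mean(y1) - mean(y0)) / s, length(y1), length(y0))
}

#' Unmatched comparator effect
#'
#' The same standardized mean difference computed over all of the subject's
#' paired days, without any matching.
#'
#' @param outcome Outcome vector.
#' @param treatment Integer 0/1 vector.
#' @return One-row tibble as in [personal_effect()].
#' @export
unmatched_effect <- function(outcome, treatment) {
  y1 <- outcome[treatment == 1L]
  y0 <- outcome[treatment == 0L]
  if (!length(y1) || !length(y0)) return(effect_row(reason = "single_class"))
  s <- pooled_sd(y1, y0)
  if (!is.finite(s) || s == 0)
    return(effect_row(n1 = length(y1), n0 = length(y0),
                      reason = "degenerate_outcome"))
  effect_row((mean(y1) - mean(y0)) / s, length(y1), length(y0))
}

#' Covariate balance diagnostics for one subject
#'
#' For every confounder: the point-biserial correlation with the binary
#' treatment before matching (with its test p-value), and the standardized
#' mean difference between treatment classes before and after matching.
#' Categorical confounders enter as numeric codes (day of week 1-7; day type
#' normal/partial/off as 0/1/2).
#'
#' @param rows One subject's lagged day rows.
#' @param treatment Integer 0/1 vector.
#' @param pairs Matched pairs from [match_pairs()] (may have zero rows).
#' @return Tibble with one row per confounder: `confounder`, `cor_pre`,
#'   `p_value`, `smd_pre`, `smd_post`.
#' @export
balance_report <- function(rows, treatment, pairs) {
  codes <- balance_codes(rows)
  purrr::map_dfr(names(codes), function(v) {
    x <- codes[[v]]
    ct <- if (stats::sd(x) > 0 && stats::sd(treatment) > 0)
      suppressWarnings(stats::cor.test(x, treatment)) else NULL
    post <- if (nrow(pairs)) {
      idx <- c(pairs$treated, pairs$control)
      smd(x[idx], c(rep(1L, nrow(pairs)), rep(0L, nrow(pairs))))
    } else NA_real_
    tibble::tibble(
      confounder = v,
      cor_pre = if (is.null(ct)) 0 else unname(ct$estimate),
      p_value = if (is.null(ct)) NA_real_ else ct$p.value,
      smd_pre = smd(x, treatment) %||% NA_real_,
      smd_post = post
    )
  })
}

balance_codes <- function(rows) {
  codes <- as.list(rows[, intersect(.confounder_num, names(rows)), drop = FALSE])
  lag_cols <- grep("^(mood|sleep)_lag[0-9]+$", names(rows), value = TRUE)
  codes <- c(codes, as.list(rows[, lag_cols, drop = FALSE]))
  if ("day_of_week" %in% names(rows))
    codes$day_of_week <- as.numeric(rows$day_of_week)
  if ("day_type" %in% names(rows))
    codes$day_type <- as.numeric(factor(rows$day_type,
                                        levels = c("normal", "partial", "off"))) - 1
  lapply(codes, as.numeric)
}

#' Per-subject personal causal effects for a whole cohort
#'
#' Runs the full per-subject pipeline for one direction and history depth:
#' treatment-variance exclusion, lagged-row construction, binarization at
#' the subject mean, ridge-logistic propensity estimation, greedy 1:1
#' matching, and the standardized matched (or unmatched) effect. Every
#' exclusion is recorded with its reason rather than silently dropped.
#'
#' @param daily A daily panel tibble (see [aggregate_daily()]).
#' @param direction `"sleep_to_mood"` or `"mood_to_sleep"`.
#' @param config A [psm_config()].
#' @param matched Compute the matched effect (`TRUE`, default) or the
#'   unmatched comparator over all paired days (`FALSE`).
#' @param confounder_timing Passed to [build_lagged_dataset()].
#' @return Tibble with one row per subject: `subject_id`, `group`,
#'   `direction`, `T`, `matched`, `effect`, counts, `n_rows`,
#'   `excluded_reason` (`NA` for valid estimates).
#' @export
subject_effects <- function(daily, direction, config = psm_config(),
                            matched = TRUE,
                            confounder_timing = "before_outcome") {
  direction <- match_direction(direction)
  treat_var <- if (direction == "sleep_to_mood") "sleep_quality" else "mood"
  lowvar <- filter_low_variance(daily, treat_var,
                                threshold = config$variance_threshold)
  lagged <- build_lagged_dataset(
    lowvar$kept, direction, T = if (matched) config$T else 0,
    confounder_timing = confounder_timing,
    require_confounders = matched)
  groups <- daily |> dplyr::distinct(.data$subject_id, .data$group)

  per_subject <- lagged |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(rows, key) {
      sseed <- derive_seed(config$seed %||% 1L,
                          sum(utf8ToInt(as.character(key$subject_id[[1]]))))
      tr <- binarize_treatment(rows$treatment, tie_rule = config$tie_rule)
      res <- if (!any(tr == 1L) || !any(tr == 0L)) {
        effect_row(reason = "single_class")
      } else if (!matched) {
        unmatched_effect(rows$outcome, tr)
      } else if (min(sum(tr == 1L), sum(tr == 0L)) < 2L) {
        effect_row(reason = "too_few_per_class")
      } else {
        ps <- estimate_propensity(rows, tr, ridge = config$ridge)
        cfg <- config; cfg$seed <- sseed
        pairs <- match_pairs(ps$scores, tr, cfg)
        personal_effect(rows$outcome, pairs)
      }
      res$n_rows <- nrow(rows)
      res
    }) |>
    dplyr::ungroup()

  excluded_lowvar <- lowvar$excluded |>
    dplyr::transmute(subject_id = .data$subject_id, effect = NA_real_,
                     n_treated_matched = NA_integer_,
                     n_control_matched = NA_integer_,
                     excluded_reason = "low_variance", n_rows = NA_integer_)
  # subjects whose rows all vanished in lag construction
  gone <- setdiff(lowvar$kept$subject_id,
                  c(per_subject$subject_id, excluded_lowvar$subject_id))
  excluded_gone <- tibble::tibble(
    subject_id = gone, effect = NA_real_, n_treated_matched = NA_integer_,
    n_control_matched = NA_integer_, excluded_reason = "no_rows",
    n_rows = 0L)

  dplyr::bind_rows(per_subject, excluded_lowvar, excluded_gone) |>
    dplyr::left_join(groups, by = "subject_id") |>
    dplyr::mutate(direction = direction, T = if (matched) config$T else 0L,
                  matched = matched) |>
    dplyr::select("subject_id", "group", "direction", "T", "matched",
                  "effect", "n_treated_matched", "n_control_matched",
                  "n_rows", "excluded_reason") |>
    dplyr::arrange(.data$subject_id)
}

#' Cohort-level balance summary
#'
#' Runs [balance_report()] for every analyzable subject and averages:
#' per confounder, the mean and SD of the pre-match treatment correlation,
#' the number of subjects with a correlation p-value below .05, and the mean
#' absolute standardized mean difference before and after matching.
#'
#' @inheritParams subject_effects
#' @return List with `per_subject` (stacked balance tables) and `summary`
#'   (one row per confounder).
#' @export
cohort_balance <- function(daily, direction, config = psm_config(),
                           confounder_timing = "before_outcome") {
  direction <- match_direction(direction)
  treat_var <- if (direction == "sleep_to_mood") "sleep_quality" else "mood"
  lowvar <- filter_low_variance(daily, treat_var,
                                threshold = config$variance_threshold)
  lagged <- build_lagged_dataset(lowvar$kept, direction, T = config$T,
                                 confounder_timing = confounder_timing)
  per_subject <- lagged |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(rows, key) {
      tr <- binarize_treatment(rows$treatment, tie_rule = config$tie_rule)
      if (!any(tr == 1L) || !any(tr == 0L) ||
          min(sum(tr == 1L), sum(tr == 0L)) < 2L)
        return(tibble::tibble())
      ps <- estimate_propensity(rows, tr, ridge = config$ridge)
      cfg <- config
      cfg$seed <- derive_seed(config$seed %||% 1L,
                              sum(utf8ToInt(as.character(key$subject_id[[1]]))))
      pairs <- match_pairs(ps$scores, tr, cfg)
      balance_report(rows, tr, pairs)
    }) |>
    dplyr::ungroup()
  summary <- per_subject |>
    dplyr::group_by(.data$confounder) |>
    dplyr::summarise(
      cor_mean = mean(.data$cor_pre, na.rm = TRUE),
      cor_sd = stats::sd(.data$cor_pre, na.rm = TRUE),
      n_p_below_05 = sum(.data$p_value < 0.05, na.rm = TRUE),
      mean_abs_smd_pre = mean(abs(.data$smd_pre), na.rm = TRUE),
      mean_abs_smd_post = mean(abs(.data$smd_post), na.rm = TRUE),
      n_subjects = dplyr::n(),
      .groups = "drop")
  list(per_subject = per_subject, summary = summary)
}
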