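#' Simulation configuration for a synthetic EMA cohort
#'
#' Collects and validates every knob of the synthetic diary-cohort generator.
#' Defaults emulate the design of a six-week mobile-phone EMA study: four
#' symptom groups of roughly 52 adults each, 42 planned diary days, a
#' sleep-to-mood coupling substantially stronger than the reverse, modest
#' day-to-day persistence, Table-able shared daily confounding, and roughly a
#' fifth of diary days missing.
#'
#' @param n_subjects_per_group Subjects per symptom group (four groups:
#'   control, depressed, anxious, depressed_anxious). Default 52.
#' @param n_days Planned diary days per subject. Default 42 (six weeks).
#' @param beta_sleep_to_mood Latent standardized cross-lag coefficient of the
#'   night's sleep quality on same-day mood. Default 0.35.
#' @param beta_mood_to_sleep Latent standardized cross-lag coefficient of
#'   daytime mood on the following night's sleep quality. Default 0.13.
#' @param ar_mood,ar_sleep Autoregressive (day-to-day persistence)
#'   coefficients of the two latent series, each in `[0, 1)`. Default 0.1:
#'   persistence is kept modest so the marginal lag-1 standardized association
#'   stays dominated by the cross-lag coupling and the generative coefficient
#'   remains interpretable as ground truth.
#' @param confounder_strength Loading of the shared daily confounder `c(t)`
#'   on both latent series. `c(t)` is also emitted (with noise) as the
#'   observable stress, energy, and focus ratings, so these are genuine
#'   measured confounders. Default 0.3.
#' @param noise_sd Innovation standard deviation of both latent series.
#'   Default 1.
#' @param missing_prob Probability that a diary day is absent, independently
#'   per day (MCAR). Default 0.2.
#' @param seed Integer master seed; identical config + seed reproduces the
#'   cohort bit-identically.
#' @param report_sd Standard deviation of the within-day re-rating noise
#'   added to the latent value before each Likert mapping. Default 0.25.
#' @param style_shift_sd,style_scale_sdlog Spread of the per-subject
#'   reporting style: additive shifts are `N(0, style_shift_sd)` and
#'   multiplicative scales are `LogNormal(log 1.3, style_scale_sdlog)`.
#' @param group_effects Optional named list overriding the cross-lag
#'   coefficients for particular groups, e.g.
#'   `list(anxious = list(beta_mood_to_sleep = 0.26))`.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects_per_group = 2, n_days = 10, seed = 1)
#' @export
sim_config <- function(n_subjects_per_group = 52,
                       n_days = 42,
                       beta_sleep_to_mood = 0.35,
                       beta_mood_to_sleep = 0.13,
                       ar_mood = 0.1,
                       ar_sleep = 0.1,
                       confounder_strength = 0.3,
                       noise_sd = 1,
                       missing_prob = 0.2,
                       seed = 1L,
                       report_sd = 0.25,
                       style_shift_sd = 0.7,
                       style_scale_sdlog = 0.25,
                       group_effects = NULL) {
  cfg <- list(
    n_subjects_per_group = n_subjects_per_group, n_days = n_days,
    beta_sleep_to_mood = beta_sleep_to_mood,
    beta_mood_to_sleep = beta_mood_to_sleep,
    ar_mood = ar_mood, ar_sleep = ar_sleep,
    confounder_strength = confounder_strength, noise_sd = noise_sd,
    missing_prob = missing_prob, seed = seed, report_sd = report_sd,
    style_shift_sd = style_shift_sd, style_scale_sdlog = style_scale_sdlog,
    group_effects = group_effects
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v))
      stop_field(field, "must be a single integer >= 1")
  }
  chk_num <- function(field, lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok)
      stop_field(field, sprintf("must be a single number in %s%s, %s%s",
                                if (lo_open) "(" else "[", lo, hi,
                                if (hi_open) ")" else "]"))
  }
  chk_count("n_subjects_per_group")
  chk_count("n_days")
  chk_num("beta_sleep_to_mood", -2, 2)
  chk_num("beta_mood_to_sleep", -2, 2)
  chk_num("ar_mood", 0, 1, hi_open = TRUE)
  chk_num("ar_sleep", 0, 1, hi_open = TRUE)
  chk_num("confounder_strength", -5, 5)
  chk_num("noise_sd", 0, Inf)
  chk_num("missing_prob", 0, 1, hi_open = TRUE)
  chk_num("report_sd", 0, Inf)
  chk_num("style_shift_sd", 0, Inf)
  chk_num("style_scale_sdlog", 0, Inf)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_field("seed", "must be a single integer")
  if (!is.null(cfg$group_effects)) {
    if (!is.list(cfg$group_effects) ||
        !all(names(cfg$group_effects) %in% .group_names))
      stop_field("group_effects",
                 "must be a named list keyed by group name")
    bad <- unlist(lapply(cfg$group_effects, function(g)
      setdiff(names(g), c("beta_sleep_to_mood", "beta_mood_to_sleep"))))
    if (length(bad))
      stop_field("group_effects", paste("unknown coefficient:", bad[[1]]))
  }
  invisible(cfg)
}

.group_names <- c("control", "depressed", "anxious", "depressed_anxious")

# Screening-score sampling parameters per group: truncated normals matching
# the study design's reported group means/SDs, rejection-sampled to honour
# the PHQ-9 >= 10 / GAD-7 >= 10 cutoffs that define the groups.
.group_screening <- list(
  control           = list(phq9 = c(4.47, 3.05), gad7 = c(3.80, 2.95),
                           phq9_rng = c(0, 9),  gad7_rng = c(0, 9)),
  depressed         = list(phq9 = c(13.40, 2.90), gad7 = c(5.94, 2.43),
                           phq9_rng = c(10, 27), gad7_rng = c(0, 9)),
  anxious           = list(phq9 = c(7.11, 1.69), gad7 = c(13.36, 2.88),
                           phq9_rng = c(0, 9),  gad7_rng = c(10, 21)),
  depressed_anxious = list(phq9 = c(14.19, 3.45), gad7 = c(14.33, 3.06),
                           phq9_rng = c(10, 27), gad7_rng = c(10, 21))
)

# integer truncated-normal draw by rejection, with a safety fallback
rtrunc_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  for (i in 1:200) {
    x <- round_half_up(rnorm(n * 2, mean, sd))
    x <- x[x >= lo & x <= hi]
    out <- c(out, x)
    if (length(out) >= n) return(as.integer(out[seq_len(n)]))
  }
  as.integer(pmin(hi, pmax(lo, round_half_up(rnorm(n, mean, sd)))))
}

#' Construct a symptom-group label with screening scores
#'
#' @param name One of `"control"`, `"depressed"`, `"anxious"`,
#'   `"depressed_anxious"`.
#' @param phq9 Integer depression screening score, 0-27.
#' @param gad7 Integer anxiety screening score, 0-21.
#' @return A list of class `group_label`. The combination must satisfy the
#'   group cutoffs (depressed iff PHQ-9 >= 10, anxious iff GAD-7 >= 10).
#' @export
group_label <- function(name, phq9, gad7) {
  name <- rlang::arg_match0(name, .group_names)
  if (!is.numeric(phq9) || phq9 < 0 || phq9 > 27 || phq9 != floor(phq9))
    stop_field("phq9", "must be an integer in [0, 27]")
  if (!is.numeric(gad7) || gad7 < 0 || gad7 > 21 || gad7 != floor(gad7))
    stop_field("gad7", "must be an integer in [0, 21]")
  implied <- group_from_scores(phq9, gad7)
  if (implied != name)
    stop_field("name", sprintf(
      "scores phq9=%d, gad7=%d imply group '%s'", phq9, gad7, implied))
  structure(list(name = name, phq9 = as.integer(phq9), gad7 = as.integer(gad7)),
            class = "group_label")
}

#' @rdname group_label
#' @export
group_from_scores <- function(phq9, gad7) {
  dplyr::case_when(
    phq9 >= 10 & gad7 >= 10 ~ "depressed_anxious",
    phq9 >= 10 ~ "depressed",
    gad7 >= 10 ~ "anxious",
    TRUE ~ "control"
  )
}

#' Construct a subject reporting style
#'
#' A reporting style is the affine response bias of one subject: observed
#' Likert ratings are `round(clip(4 + scale * latent + shift, 0, 8))`.
#'
#' @param shift Additive offset on the latent-to-Likert map.
#' @param scale Positive multiplicative factor.
#' @return A list of class `reporting_style`.
#' @export
reporting_style <- function(shift = 0, scale = 1) {
  if (!is.numeric(shift) || length(shift) != 1L || is.na(shift))
    stop_field("shift", "must be a single number")
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop_field("scale", "must be a single positive number")
  structure(list(shift = shift, scale = scale), class = "reporting_style")
}
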