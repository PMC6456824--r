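#' Bar chart of the history-depth sweep
#'
#' Mean personal causal effect per arm (unmatched, then matched at each
#' history depth), one bar group per direction, with bootstrap-SD error
#' bars.
#'
#' @param summaries A summaries tibble from [run_T_sweep()] (one or both
#'   directions stacked).
#' @return A ggplot object.
#' @export
plot_effect_sweep <- function(summaries) {
  arms <- unique(summaries$arm)
  summaries |>
    dplyr::mutate(arm = factor(.data$arm, levels = arms)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$arm, y = .data$mean_effect,
                                 fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7,
                      color = "grey20") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_effect - .data$sd_effect,
                   ymax = .data$mean_effect + .data$sd_effect),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::scale_fill_grey(start = 0.95, end = 0.55) +
    ggplot2::labs(x = "matching arm (history depth)",
                  y = "mean personal causal effect (SMD)",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Bar chart of group-wise personal effects
#'
#' Mean personal causal effect per symptom group and direction, with
#' bootstrap-SD error bars computed by resampling subjects within group.
#'
#' @param effects A per-subject effect tibble (one matching arm) carrying
#'   `group` labels.
#' @param n_boot,seed Bootstrap settings for the per-group error bars.
#' @return A ggplot object.
#' @export
plot_group_effects <- function(effects, n_boot = 100, seed = 1L) {
  sums <- effects |>
    dplyr::filter(is.na(.data$excluded_reason), is.finite(.data$effect)) |>
    dplyr::group_by(.data$direction, .data$group) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::group_modify(function(d, key)
      bootstrap_mean_effect(dplyr::mutate(d, excluded_reason = NA_character_),
                            n_boot = n_boot,
                            seed = derive_seed(seed, nrow(d))) |>
        dplyr::select("mean_effect", "sd_effect")) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = factor(.data$group, levels = .group_names))
  ggplot2::ggplot(sums, ggplot2::aes(x = .data$group, y = .data$mean_effect,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7,
                      color = "grey20") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_effect - .data$sd_effect,
                   ymax = .data$mean_effect + .data$sd_effect),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::scale_fill_grey(start = 0.95, end = 0.55) +
    ggplot2::labs(x = "symptom group",
                  y = "mean personal causal effect (SMD)",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
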