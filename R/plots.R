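#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pathway recruitment probabilities
#'
#' Bar chart of the mean probability that a starting seed becomes a newly
#' emerged and a surviving seedling, by pathway, with +/- 1 bootstrap-SE error
#' bars.
#'
#' @param object A `seed_fate_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seed_fate_result <- function(object, ...) {
  dat <- object$summaries |>
    dplyr::filter(.data$quantity %in% c("p_newly_emerged", "p_surviving")) |>
    dplyr::mutate(quantity = dplyr::recode(
      .data$quantity,
      p_newly_emerged = "Newly emerged seedlings",
      p_surviving = "Surviving seedlings"
    ))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$quantity, y = .data$mean, fill = .data$pathway
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$se, 0),
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Probability per starting seed",
                  fill = "Pathway") +
    ggplot2::theme_minimal()
}

#' Plot the seed-fate decomposition
#'
#' Stacked bars of the starting-seed-scale fate fractions (predated, never
#' emerged, emerged but died, surviving) for each pathway.
#'
#' @param result A `seed_fate_result`.
#' @return A ggplot object.
#' @export
plot_seed_fate <- function(result) {
  stopifnot(inherits(result, "seed_fate_result"))
  dat <- seed_fate_fractions(result) |>
    tidyr::pivot_longer(-"pathway", names_to = "fate", values_to = "fraction") |>
    dplyr::mutate(fate = factor(
      .data$fate,
      levels = c("surviving", "emerged_died", "ungerminated", "predated"),
      labels = c("Surviving seedling", "Seedling died",
                 "Never emerged", "Predated")
    ))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$pathway, y = .data$fraction, fill = .data$fate
  )) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "Fraction of starting seeds", fill = "Fate") +
    ggplot2::theme_minimal()
}

#' Plot a microhabitat-selection index
#'
#' Deposition selection per microhabitat (dropping percentage minus cover
#' percentage, in percentage points) with bootstrap intervals; values above
#' zero indicate preferential deposition.
#'
#' @param object A `selection_index`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_index <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$microhabitat, y = .data$index)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ci_low, ymax = .data$ci_high, colour = .data$selection
    )) +
    ggplot2::scale_colour_manual(values = c(
      positive = "#2166ac", negative = "#b2182b", none = "grey40"
    )) +
    ggplot2::labs(x = NULL, y = "Droppings % - cover % (points)",
                  colour = "Selection") +
    ggplot2::theme_minimal()
}

#' Plot replicate-level transition probabilities
#'
#' Jittered replicate proportions per microhabitat (and treatment when
#' relevant), faceted by stage — the raw material the simulation resamples.
#'
#' @param object A `transition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_table <- function(object, ...) {
  dat <- as_tibble(object) |>
    dplyr::mutate(treatment = dplyr::coalesce(.data$treatment, "(all)"))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$microhabitat, y = .data$proportion, colour = .data$treatment
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 3,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Replicate-level proportion",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}
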