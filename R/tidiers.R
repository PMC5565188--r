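#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a seed-fate simulation result
#'
#' One row per pathway x quantity with the iteration mean and bootstrap SE.
#'
#' @param x A `seed_fate_result`.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `quantity`, `mean`, `se`.
#' @export
tidy.seed_fate_result <- function(x, ...) {
  x$summaries
}

#' One-row summary of a seed-fate simulation
#'
#' @param x A `seed_fate_result`.
#' @param ... Unused.
#' @return A one-row tibble: iteration count, modes and the two advantage
#'   ratios.
#' @export
glance.seed_fate_result <- function(x, ...) {
  adv <- dispersal_advantage(x)
  tibble(
    n_iterations = x$config$n_iterations,
    iteration_draw_mode = x$config$iteration_draw_mode,
    weighting_mode = x$config$weighting_mode,
    advantage_newly_emerged = adv$ratio[adv$quantity == "p_newly_emerged"],
    advantage_surviving = adv$ratio[adv$quantity == "p_surviving"]
  )
}

#' Tidy a microhabitat-selection index
#'
#' @param x A `selection_index`.
#' @param ... Unused.
#' @return The underlying tibble (one row per microhabitat).
#' @export
tidy.selection_index <- function(x, ...) {
  as_tibble(x)
}

#' Tidy or summarise a parameter-recovery report
#'
#' `tidy()` returns the per-quantity bias/RMSE table; `glance()` a one-row
#' overview.
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  adv <- x$summary[x$summary$quantity == "advantage_newly", ]
  tibble(
    n_datasets = x$n_datasets,
    seed = x$seed,
    advantage_truth = adv$truth,
    advantage_relative_bias = adv$relative_bias
  )
}
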