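#' Configure the seed-fate simulation
#'
#' @param n_iterations Number of bootstrap iterations (default 500).
#' @param rng_seed Integer seed; every random draw of the run flows from this
#'   single seed, so identical configurations give bit-identical results.
#' @param iteration_draw_mode How each stage's transition probability is drawn
#'   per iteration: `"single_replicate"` (default) picks one replicate-level
#'   proportion uniformly at random with replacement; `"resampled_mean"`
#'   resamples the whole replicate list with replacement to its own size and
#'   uses its mean.
#' @param weighting_mode How per-microhabitat contributions of the dispersed
#'   pathway are combined: `"dispersal_only"` (default) uses the deposition
#'   probabilities directly; `"dispersal_times_cover"` multiplies them by the
#'   relative cover of each microhabitat and renormalizes.
#' @param undispersed_treatment_mix Named weights over `RED` and `YELLOW`
#'   giving the fruit-morph composition of undispersed seeds (default
#'   `c(RED = 0.8, YELLOW = 0.2)`: red fruits are four times as frequent as
#'   yellow ones).
#' @return A `simulation_config` object.
#' @export
#' @examples
#' simulation_config(n_iterations = 1000, rng_seed = 42)
simulation_config <- function(n_iterations = 500,
                              rng_seed = 1,
                              iteration_draw_mode = c("single_replicate", "resampled_mean"),
                              weighting_mode = c("dispersal_only", "dispersal_times_cover"),
                              undispersed_treatment_mix = c(RED = 0.8, YELLOW = 0.2)) {
  n_iterations <- check_count(n_iterations, "n_iterations")
  iteration_draw_mode <- match.arg(iteration_draw_mode)
  weighting_mode <- match.arg(weighting_mode)
  mix <- undispersed_treatment_mix
  if (is.null(names(mix)) || !setequal(names(mix), c("RED", "YELLOW"))) {
    abort_config("`undispersed_treatment_mix` must be named with RED and YELLOW.")
  }
  mix <- mix[c("RED", "YELLOW")]
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    abort_config("Treatment-mix weights must be >= 0 and sum to 1.")
  }
  structure(
    list(
      n_iterations = n_iterations,
      rng_seed = if (is.null(rng_seed)) NULL else check_count(rng_seed, "rng_seed", min = -.Machine$integer.max),
      iteration_draw_mode = iteration_draw_mode,
      weighting_mode = weighting_mode,
      undispersed_treatment_mix = mix
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  iterations: %d  seed: %s\n", x$n_iterations,
              x$rng_seed %||% "<global RNG>"))
  cat(sprintf("  draw mode:  %s\n  weighting:  %s\n",
              x$iteration_draw_mode, x$weighting_mode))
  cat(sprintf("  undispersed mix: RED %.2f / YELLOW %.2f\n",
              x$undispersed_treatment_mix[["RED"]],
              x$undispersed_treatment_mix[["YELLOW"]]))
  invisible(x)
}

#' Chain one microhabitat's stage probabilities into recruitment outcomes
#'
#' The multiplicative core of the seed-fate model: the probability that a
#' seed starting the process in a given microhabitat becomes a newly emerged
#' seedling is the product deposition x predation survival x emergence, and
#' the probability it becomes a surviving seedling multiplies in seedling
#' survival. Vectorized over its arguments.
#'
#' @param p_deposit,p_predation_survival,p_emergence,p_seedling_survival
#'   Probabilities in `[0, 1]`.
#' @return A tibble with columns `p_newly_emerged` and `p_surviving`.
#' @export
#' @examples
#' chain_product(1, 0.5, 0.5, 0.5)
chain_product <- function(p_deposit, p_predation_survival, p_emergence,
                          p_seedling_survival) {
  check_probability(p_deposit, "p_deposit")
  check_probability(p_predation_survival, "p_predation_survival")
  check_probability(p_emergence, "p_emergence")
  check_probability(p_seedling_survival, "p_seedling_survival")
  p_newly <- p_deposit * p_predation_survival * p_emergence
  tibble(
    p_newly_emerged = p_newly,
    p_surviving = p_newly * p_seedling_survival
  )
}

# Pull one group's replicate proportions out of a transition table.
transition_group <- function(tables, stage, microhabitat, treatment = NA) {
  sel <- tables$stage == stage & tables$microhabitat == microhabitat &
    (if (is.na(treatment)) is.na(tables$treatment) else
      !is.na(tables$treatment) & tables$treatment == treatment)
  props <- tables$proportion[sel]
  if (length(props) == 0) {
    abort_simulation(sprintf(
      "No replicates for stage %s, microhabitat %s%s.",
      stage, microhabitat,
      if (is.na(treatment)) "" else paste0(", treatment ", treatment)
    ))
  }
  props
}

# n_iter draws from one group's empirical distribution.
draw_stage <- function(props, n_iter, mode) {
  k <- length(props)
  if (mode == "single_replicate") {
    props[sample.int(k, n_iter, replace = TRUE)]
  } else {
    # mean of a size-k resample with replacement, per iteration
    picks <- matrix(props[sample.int(k, n_iter * k, replace = TRUE)], nrow = k)
    colMeans(picks)
  }
}

# Deposition weights of the dispersed pathway under the configured weighting.
dispersal_weights <- function(dispersal, cover, weighting_mode) {
  w <- setNames(dispersal$prob, dispersal$microhabitat)
  if (weighting_mode == "dispersal_times_cover") {
    if (is.null(cover)) {
      abort_config("`cover` is required under weighting_mode = 'dispersal_times_cover'.")
    }
    cover <- validate_cover_table(cover)
    cv <- setNames(cover$cover, cover$microhabitat)
    missing <- setdiff(names(w), names(cv))
    if (length(missing) > 0) {
      abort_simulation(sprintf(
        "Cover table lacks microhabitat(s) %s.", paste(missing, collapse = ", ")
      ))
    }
    w <- w * cv[names(w)]
    if (sum(w) <= 0) abort_simulation("All cover-weighted deposition weights are zero.")
    w <- w / sum(w)
  }
  w
}

#' Run the stochastic seed-fate simulation
#'
#' Bootstrap simulation of seed fate through the stage-structured recruitment
#' model, for two pathways:
#'
#' * **Dispersed**: seeds pass through the disperser's gut (treatment
#'   `DIGESTED`) and are deposited across microhabitats according to
#'   `dispersal` (optionally re-weighted by relative cover). Per iteration,
#'   each microhabitat's predation-survival, emergence and seedling-survival
#'   probabilities are drawn from their empirical replicate distributions and
#'   chained multiplicatively; the pathway outcome is the deposition-weighted
#'   sum over microhabitats.
#' * **Undispersed**: seeds fall beneath the mother plant, so deposition is a
#'   point mass on `EPHEDRA`; stage draws use the `RED`/`YELLOW` treatment
#'   tables mixed by the configured fruit-morph weights (each seed follows its
#'   own morph's emergence and survival).
#'
#' Stage draws are independent across stages and microhabitats within an
#' iteration. The run is fully reproducible under a fixed `rng_seed`.
#'
#' @param tables A `transition_table` covering all three stages (see
#'   [transition_tables()]).
#' @param dispersal A `dispersal_distribution` for Stage 1 (see
#'   [estimate_dispersal_distribution()]).
#' @param cover A [cover_table()]; required only under
#'   `weighting_mode = "dispersal_times_cover"`.
#' @param config A [simulation_config()].
#' @return A `seed_fate_result` object: `$iterations` (per-iteration pathway
#'   outcomes, including the aggregate predation survival used for the
#'   stage-loss decomposition), `$summaries` (mean and bootstrap SE — the
#'   standard deviation across iterations — of each quantity), `$weights`
#'   (the deposition weights used) and `$config`. Use [tidy()],
#'   [glance()], [stage_loss_decomposition()] and [dispersal_advantage()] to
#'   interrogate it.
#' @seealso [analytic_expected_outcome()] for the closed-form expectation of
#'   the simulation mean.
#' @export
#' @examples
#' ds <- generate_field_dataset(paper_like_truth(), paper_design(), seed = 1)
#' res <- run_seed_fate_simulation(
#'   transition_tables(ds),
#'   estimate_dispersal_distribution(ds),
#'   cover = ds$cover,
#'   config = simulation_config(n_iterations = 500, rng_seed = 1)
#' )
#' res
run_seed_fate_simulation <- function(tables, dispersal, cover = NULL,
                                     config = simulation_config()) {
  tables <- new_transition_table(tables)
  dispersal <- new_dispersal_distribution(dispersal)
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a simulation_config().")
  }
  n_iter <- config$n_iterations
  mode <- config$iteration_draw_mode
  mix <- config$undispersed_treatment_mix
  w <- dispersal_weights(dispersal, cover, config$weighting_mode)
  active <- names(w)[w > 0]
  if (length(active) == 0) abort_simulation("No microhabitat has positive deposition weight.")

  # Pre-fetch every needed group so missing groups error before any draw.
  groups_d <- lapply(active, function(m) list(
    s2 = transition_group(tables, "PREDATION_SURVIVAL", m),
    s3 = transition_group(tables, "EMERGENCE", m, "DIGESTED"),
    s4 = transition_group(tables, "SEEDLING_SURVIVAL", m, "DIGESTED")
  ))
  names(groups_d) <- active
  morphs <- names(mix)[mix > 0]
  groups_u <- list(
    s2 = transition_group(tables, "PREDATION_SURVIVAL", "EPHEDRA"),
    per_morph = lapply(setNames(morphs, morphs), function(t) list(
      s3 = transition_group(tables, "EMERGENCE", "EPHEDRA", t),
      s4 = transition_group(tables, "SEEDLING_SURVIVAL", "EPHEDRA", t)
    ))
  )

  sim <- with_seed_if(config$rng_seed, {
    # Dispersed pathway: deposition-weighted sums over microhabitats.
    d_s2 <- d_newly <- d_surv <- numeric(n_iter)
    for (m in active) {
      g <- groups_d[[m]]
      s2 <- draw_stage(g$s2, n_iter, mode)
      s3 <- draw_stage(g$s3, n_iter, mode)
      s4 <- draw_stage(g$s4, n_iter, mode)
      d_s2 <- d_s2 + w[[m]] * s2
      d_newly <- d_newly + w[[m]] * s2 * s3
      d_surv <- d_surv + w[[m]] * s2 * s3 * s4
    }
    # Undispersed pathway: point mass on EPHEDRA, morph-mixed treatments.
    u_s2 <- draw_stage(groups_u$s2, n_iter, mode)
    u_newly <- u_surv <- numeric(n_iter)
    for (t in morphs) {
      g <- groups_u$per_morph[[t]]
      s3 <- draw_stage(g$s3, n_iter, mode)
      s4 <- draw_stage(g$s4, n_iter, mode)
      u_newly <- u_newly + mix[[t]] * u_s2 * s3
      u_surv <- u_surv + mix[[t]] * u_s2 * s3 * s4
    }
    list(d_s2 = d_s2, d_newly = d_newly, d_surv = d_surv,
         u_s2 = u_s2, u_newly = u_newly, u_surv = u_surv)
  })

  iterations <- dplyr::bind_rows(
    tibble(
      iteration = seq_len(n_iter), pathway = "DISPERSED",
      p_predation_survival = sim$d_s2,
      p_newly_emerged = sim$d_newly, p_surviving = sim$d_surv
    ),
    tibble(
      iteration = seq_len(n_iter), pathway = "UNDISPERSED",
      p_predation_survival = sim$u_s2,
      p_newly_emerged = sim$u_newly, p_surviving = sim$u_surv
    )
  )
  summaries <- iterations |>
    tidyr::pivot_longer(
      c("p_predation_survival", "p_newly_emerged", "p_surviving"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::group_by(.data$pathway, .data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value),
      .groups = "drop"
    )

  structure(
    list(iterations = iterations, summaries = summaries,
         weights = tibble(microhabitat = names(w), weight = unname(w)),
         config = config),
    class = "seed_fate_result"
  )
}

#' @export
print.seed_fate_result <- function(x, ...) {
  cat(sprintf(
    "<seed_fate_result>  %d iterations, draw mode '%s', weighting '%s'\n",
    x$config$n_iterations, x$config$iteration_draw_mode, x$config$weighting_mode
  ))
  s <- x$summaries |>
    dplyr::filter(.data$quantity != "p_predation_survival") |>
    dplyr::mutate(
      label = sprintf("%s %s: %.5f (SE %.5f)", .data$pathway,
                      sub("^p_", "", .data$quantity), .data$mean, .data$se)
    )
  cat(paste0("  ", s$label, collapse = "\n"), "\n")
  adv <- dispersal_advantage(x)
  cat(sprintf("  advantage (newly emerged): %s\n",
              format_ratio(adv$ratio[adv$quantity == "p_newly_emerged"])))
  cat(sprintf("  advantage (surviving):     %s\n",
              format_ratio(adv$ratio[adv$quantity == "p_surviving"])))
  invisible(x)
}

format_ratio <- function(r) {
  if (is.na(r)) "undefined (both pathway means are 0)"
  else if (is.infinite(r)) "infinite (no undispersed success)"
  else sprintf("%.2f", r)
}

#' Closed-form expectation of the simulation mean
#'
#' Under independent stage draws, the expected pathway outcome equals the
#' chained, deposition-weighted product evaluated at the per-group replicate
#' means (for both draw modes, since a bootstrap-resample mean is unbiased for
#' the group mean). This is the analytic oracle against which the stochastic
#' simulation's convergence is checked.
#'
#' @inheritParams run_seed_fate_simulation
#' @return A tibble with one row per pathway: `p_newly_emerged`,
#'   `p_surviving`.
#' @export
analytic_expected_outcome <- function(tables, dispersal, cover = NULL,
                                      config = simulation_config()) {
  tables <- new_transition_table(tables)
  dispersal <- new_dispersal_distribution(dispersal)
  w <- dispersal_weights(dispersal, cover, config$weighting_mode)
  active <- names(w)[w > 0]
  gmean <- function(stage, m, t = NA) mean(transition_group(tables, stage, m, t))
  d_newly <- sum(vapply(active, function(m) {
    w[[m]] * gmean("PREDATION_SURVIVAL", m) * gmean("EMERGENCE", m, "DIGESTED")
  }, numeric(1)))
  d_surv <- sum(vapply(active, function(m) {
    w[[m]] * gmean("PREDATION_SURVIVAL", m) * gmean("EMERGENCE", m, "DIGESTED") *
      gmean("SEEDLING_SURVIVAL", m, "DIGESTED")
  }, numeric(1)))
  mix <- config$undispersed_treatment_mix
  morphs <- names(mix)[mix > 0]
  u_s2 <- gmean("PREDATION_SURVIVAL", "EPHEDRA")
  u_newly <- u_s2 * sum(vapply(morphs, function(t) {
    mix[[t]] * gmean("EMERGENCE", "EPHEDRA", t)
  }, numeric(1)))
  u_surv <- u_s2 * sum(vapply(morphs, function(t) {
    mix[[t]] * gmean("EMERGENCE", "EPHEDRA", t) *
      gmean("SEEDLING_SURVIVAL", "EPHEDRA", t)
  }, numeric(1)))
  tibble(
    pathway = c("DISPERSED", "UNDISPERSED"),
    p_newly_emerged = c(d_newly, u_newly),
    p_surviving = c(d_surv, u_surv)
  )
}

#' Decompose seed fate into per-stage losses
#'
#' For each pathway, the mean (over iterations) of the per-iteration
#' conditional loss at each stage: the fraction of starting seeds removed by
#' predators; of the seeds escaping predation, the fraction failing to emerge;
#' and of the emerged seedlings, the fraction dying before the final census.
#' Iterations where a conditional fraction is 0/0 (no seed reaches the stage)
#' are excluded from that stage's mean and counted in `n_undefined`.
#'
#' @param result A `seed_fate_result`.
#' @return A tibble with one row per pathway x stage: `conditional_loss`,
#'   `n_undefined`.
#' @seealso [seed_fate_fractions()] for the complementary starting-seed-scale
#'   decomposition.
#' @export
stage_loss_decomposition <- function(result) {
  stopifnot(inherits(result, "seed_fate_result"))
  mean_defined <- function(x) {
    list(mean = if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
         n_undef = sum(is.na(x)))
  }
  result$iterations |>
    dplyr::group_by(.data$pathway) |>
    dplyr::group_modify(function(df, key) {
      s2 <- df$p_predation_survival
      emerge <- ifelse(s2 > 0, df$p_newly_emerged / s2, NA_real_)
      surv <- ifelse(df$p_newly_emerged > 0,
                     df$p_surviving / df$p_newly_emerged, NA_real_)
      pred <- mean_defined(1 - s2)
      eme <- mean_defined(1 - emerge)
      dea <- mean_defined(1 - surv)
      tibble(
        stage = c("PREDATION", "EMERGENCE_FAILURE", "SEEDLING_MORTALITY"),
        conditional_loss = c(pred$mean, eme$mean, dea$mean),
        n_undefined = c(pred$n_undef, eme$n_undef, dea$n_undef)
      )
    }) |>
    dplyr::ungroup()
}

#' Seed fate on the starting-seed scale
#'
#' Splits each starting seed's probability mass into the four terminal fates:
#' predated, surviving predation but never emerging, emerging but dying as a
#' seedling, and surviving as a seedling. The four fractions sum to 1 in every
#' iteration by construction.
#'
#' @param result A `seed_fate_result`.
#' @param per_iteration Return per-iteration fractions instead of means.
#' @return A tibble with columns `pathway`, `predated`, `ungerminated`,
#'   `emerged_died`, `surviving` (plus `iteration` when
#'   `per_iteration = TRUE`).
#' @export
seed_fate_fractions <- function(result, per_iteration = FALSE) {
  stopifnot(inherits(result, "seed_fate_result"))
  out <- result$iterations |>
    dplyr::mutate(
      predated = 1 - .data$p_predation_survival,
      ungerminated = .data$p_predation_survival - .data$p_newly_emerged,
      emerged_died = .data$p_newly_emerged - .data$p_surviving,
      surviving = .data$p_surviving
    ) |>
    dplyr::select("iteration", "pathway", "predated", "ungerminated",
                  "emerged_died", "surviving")
  if (per_iteration) return(out)
  out |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(dplyr::across(
      c("predated", "ungerminated", "emerged_died", "surviving"), mean
    ), .groups = "drop")
}

#' Recruitment advantage of dispersal
#'
#' The ratio of pathway means (dispersed / undispersed) for the probability of
#' producing a newly emerged seedling and a surviving seedling. When the
#' undispersed mean is 0 and the dispersed mean positive the advantage is
#' reported as infinite; when both means are 0 it is undefined (`NA`).
#'
#' @param result A `seed_fate_result`.
#' @return A tibble with one row per quantity: `dispersed_mean`,
#'   `undispersed_mean`, `ratio`.
#' @export
dispersal_advantage <- function(result) {
  stopifnot(inherits(result, "seed_fate_result"))
  result$summaries |>
    dplyr::filter(.data$quantity %in% c("p_newly_emerged", "p_surviving")) |>
    dplyr::select("pathway", "quantity", "mean") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "mean") |>
    dplyr::transmute(
      quantity = .data$quantity,
      dispersed_mean = .data$DISPERSED,
      undispersed_mean = .data$UNDISPERSED,
      ratio = dplyr::case_when(
        .data$UNDISPERSED > 0 ~ .data$DISPERSED / .data$UNDISPERSED,
        .data$DISPERSED > 0 ~ Inf,
        TRUE ~ NA_real_
      )
    )
}
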