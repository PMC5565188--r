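#' Save and load estimated model inputs as JSON
#'
#' Serializes the three-stage transition table, the dispersal distribution and
#' (optionally) the cover table so simulations can be run from saved estimates
#' without the raw field data.
#'
#' @param tables A `transition_table` (see [transition_tables()]).
#' @param dispersal A `dispersal_distribution`.
#' @param cover Optional [cover_table()].
#' @param path JSON file path.
#' @return `write_estimates_json()` returns `path` invisibly;
#'   `read_estimates_json()` returns a list with elements `tables`,
#'   `dispersal` and `cover` (possibly `NULL`).
#' @export
write_estimates_json <- function(tables, dispersal, path, cover = NULL) {
  tables <- new_transition_table(tables)
  dispersal <- new_dispersal_distribution(dispersal)
  groups <- tables |>
    dplyr::group_by(.data$stage, .data$microhabitat, .data$treatment) |>
    dplyr::summarise(proportions = list(.data$proportion), .groups = "drop")
  payload <- list(
    transition_tables = lapply(seq_len(nrow(groups)), function(i) {
      list(
        stage = groups$stage[i],
        microhabitat = groups$microhabitat[i],
        treatment = if (is.na(groups$treatment[i])) NULL else groups$treatment[i],
        proportions = groups$proportions[[i]]
      )
    }),
    dispersal = as.list(setNames(dispersal$prob, dispersal$microhabitat)),
    cover = if (is.null(cover)) NULL else {
      cover <- validate_cover_table(cover)
      as.list(setNames(cover$cover, cover$microhabitat))
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_estimates_json
#' @export
read_estimates_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: '%s'.", path))
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort_io(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)))
  )
  if (is.null(raw$transition_tables) || is.null(raw$dispersal)) {
    abort_validation("Estimates JSON must contain 'transition_tables' and 'dispersal'.")
  }
  tables <- purrr::map_dfr(raw$transition_tables, function(g) {
    props <- as.numeric(unlist(g$proportions))
    tibble(
      stage = g$stage,
      microhabitat = canon_label(g$microhabitat),
      treatment = if (is.null(g$treatment)) NA_character_ else canon_label(g$treatment),
      replicate = as.character(seq_along(props)),
      proportion = props
    )
  })
  dispersal <- new_dispersal_distribution(tibble(
    microhabitat = canon_label(names(raw$dispersal)),
    prob = as.numeric(unlist(raw$dispersal))
  ))
  cover <- NULL
  if (!is.null(raw$cover)) {
    cover <- validate_cover_table(tibble(
      microhabitat = canon_label(names(raw$cover)),
      cover = as.numeric(unlist(raw$cover))
    ))
  }
  list(tables = new_transition_table(tables), dispersal = dispersal,
       cover = cover)
}

config_as_list <- function(config) {
  list(
    n_iterations = config$n_iterations,
    rng_seed = config$rng_seed,
    iteration_draw_mode = config$iteration_draw_mode,
    weighting_mode = config$weighting_mode,
    undispersed_treatment_mix = as.list(config$undispersed_treatment_mix)
  )
}

#' Save a simulation result as JSON
#'
#' Writes the configuration echo, per-pathway summaries, stage-loss
#' decomposition, starting-seed-scale fate fractions, advantage ratios,
#' deposition weights and (optionally) the per-iteration outcome arrays.
#'
#' @param result A `seed_fate_result`.
#' @param path JSON file path.
#' @param include_iterations Also store the per-iteration arrays.
#' @return `path`, invisibly.
#' @export
write_simulation_result_json <- function(result, path,
                                         include_iterations = FALSE) {
  stopifnot(inherits(result, "seed_fate_result"))
  payload <- list(
    config = config_as_list(result$config),
    weights = as.list(setNames(result$weights$weight,
                               result$weights$microhabitat)),
    summaries = result$summaries,
    stage_losses = stage_loss_decomposition(result),
    seed_fate_fractions = seed_fate_fractions(result),
    advantage = dispersal_advantage(result)
  )
  if (include_iterations) payload$iterations <- result$iterations
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "string")
  invisible(path)
}

#' Serialize generator truth and design to a single JSON config
#'
#' Stores a [true_parameters()] object and (optionally) a [field_design()] in
#' one JSON document so a synthetic-data experiment can be replayed exactly.
#'
#' @param truth A [true_parameters()] object.
#' @param path JSON file path.
#' @param design Optional [field_design()].
#' @return `write_generator_config_json()` returns `path` invisibly;
#'   `read_generator_config_json()` returns a list with elements `truth` and
#'   `design` (`NULL` when absent).
#' @export
write_generator_config_json <- function(truth, path, design = NULL) {
  stopifnot(inherits(truth, "true_parameters"))
  payload <- list(
    truth = list(
      deposition = as.list(truth$deposition),
      stage_means = truth$stage_means,
      kappa = if (is.infinite(truth$kappa)) "Inf" else truth$kappa,
      censor_prob = truth$censor_prob,
      morph_ratio = truth$morph_ratio,
      use_distribution = as.list(truth$use_distribution)
    ),
    design = if (is.null(design)) NULL else unclass(design)
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_generator_config_json
#' @export
read_generator_config_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: '%s'.", path))
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort_io(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)))
  )
  tr <- raw$truth %||% raw
  if (is.null(tr$deposition) || is.null(tr$stage_means)) {
    abort_validation("Generator config JSON must define 'deposition' and 'stage_means'.")
  }
  sm <- as_tibble(tr$stage_means)
  if (!"treatment" %in% names(sm)) sm$treatment <- NA_character_
  sm$treatment <- as.character(sm$treatment)
  kappa <- tr$kappa %||% 12
  if (identical(kappa, "Inf")) kappa <- Inf
  truth <- true_parameters(
    deposition = unlist(tr$deposition),
    stage_means = sm,
    kappa = as.numeric(kappa),
    censor_prob = tr$censor_prob %||% 0,
    morph_ratio = tr$morph_ratio %||% 0.8,
    use_distribution = if (is.null(tr$use_distribution)) NULL else unlist(tr$use_distribution)
  )
  design <- NULL
  if (!is.null(raw$design)) design <- do.call(field_design, as.list(raw$design))
  list(truth = truth, design = design)
}

#' Write a spreadsheet-friendly summary table of a simulation result
#'
#' @param result A `seed_fate_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_simulation_summary_csv <- function(result, path) {
  stopifnot(inherits(result, "seed_fate_result"))
  readr::write_csv(result$summaries, path, progress = FALSE)
  invisible(path)
}
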