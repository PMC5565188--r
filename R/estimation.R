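new_transition_table <- function(x) {
  x <- as_tibble(x)
  require_columns(
    x, c("stage", "microhabitat", "treatment", "replicate", "proportion"),
    "transition table"
  )
  bad_stage <- setdiff(unique(x$stage), stage_levels())
  if (length(bad_stage) > 0) {
    abort_validation(sprintf(
      "Unknown stage label(s) %s.", paste0("'", bad_stage, "'", collapse = ", ")
    ))
  }
  check_probability(x$proportion, "proportion")
  structure(x, class = c("transition_table", class(tibble())))
}

#' Replicate-level transition proportions for one recruitment stage
#'
#' Converts raw tray or station records into the empirical distribution of
#' replicate-level transition probabilities that the seed-fate simulation
#' resamples:
#'
#' * `PREDATION_SURVIVAL`: each non-censored tray contributes
#'   `n_surviving / n_exposed`, grouped by microhabitat (trays carry no
#'   treatment). Censored (destroyed) trays are excluded.
#' * `EMERGENCE`: each station x treatment contributes `n_emerged / n_sown`,
#'   grouped by microhabitat and treatment.
#' * `SEEDLING_SURVIVAL`: each station x treatment with at least one emerged
#'   seedling contributes `n_surviving / n_emerged` (survival conditional on
#'   emergence); stations with zero emergence are uninformative for this
#'   stage and contribute no replicate.
#'
#' @param dataset A [field_dataset()], or a plain tibble of predation records
#'   (for `PREDATION_SURVIVAL`) / sowing records (other stages).
#' @param stage One of [stage_levels()].
#' @return A `transition_table` tibble with columns `stage`, `microhabitat`,
#'   `treatment` (`NA` for predation), `replicate` and `proportion`.
#' @seealso [transition_tables()] to build all three stages at once.
#' @export
#' @examples
#' ds <- generate_field_dataset(paper_like_truth(), paper_design(), seed = 1)
#' replicate_proportions(ds, "PREDATION_SURVIVAL")
replicate_proportions <- function(dataset, stage = stage_levels()) {
  stage <- match.arg(stage)
  records <- if (inherits(dataset, "field_dataset")) {
    if (stage == "PREDATION_SURVIVAL") dataset$predation else dataset$sowing
  } else {
    as_tibble(dataset)
  }
  if (stage == "PREDATION_SURVIVAL") {
    require_columns(
      records,
      c("tray_id", "microhabitat", "n_exposed", "n_surviving", "censored"),
      "predation records"
    )
    groups <- unique(canon_label(records$microhabitat))
    out <- records |>
      dplyr::mutate(microhabitat = canon_label(.data$microhabitat)) |>
      dplyr::filter(!.data$censored) |>
      dplyr::transmute(
        stage = stage,
        microhabitat = .data$microhabitat,
        treatment = NA_character_,
        replicate = as.character(.data$tray_id),
        proportion = .data$n_surviving / .data$n_exposed
      )
    empty <- setdiff(groups, out$microhabitat)
    if (length(empty) > 0) {
      abort_estimation(sprintf(
        "No usable replicate for %s in group(s) %s after excluding censored trays.",
        stage, paste(empty, collapse = ", ")
      ))
    }
  } else {
    require_columns(
      records,
      c("station_id", "microhabitat", "treatment", "n_sown", "n_emerged",
        "n_surviving"),
      "sowing records"
    )
    records <- records |>
      dplyr::mutate(
        microhabitat = canon_label(.data$microhabitat),
        treatment = canon_label(.data$treatment)
      )
    groups <- dplyr::distinct(records, .data$microhabitat, .data$treatment)
    if (stage == "EMERGENCE") {
      out <- records |>
        dplyr::transmute(
          stage = stage,
          microhabitat = .data$microhabitat,
          treatment = .data$treatment,
          replicate = as.character(.data$station_id),
          proportion = .data$n_emerged / .data$n_sown
        )
    } else {
      out <- records |>
        dplyr::filter(.data$n_emerged > 0) |>
        dplyr::transmute(
          stage = stage,
          microhabitat = .data$microhabitat,
          treatment = .data$treatment,
          replicate = as.character(.data$station_id),
          proportion = .data$n_surviving / .data$n_emerged
        )
    }
    empty <- dplyr::anti_join(
      groups, out, by = c("microhabitat", "treatment")
    )
    if (nrow(empty) > 0) {
      abort_estimation(sprintf(
        "No usable replicate for %s in group(s) %s.",
        stage,
        paste(paste0(empty$microhabitat, "/", empty$treatment), collapse = ", ")
      ))
    }
  }
  if (nrow(out) == 0) {
    abort_estimation(sprintf("No records available for stage %s.", stage))
  }
  new_transition_table(dplyr::arrange(
    out, .data$microhabitat, .data$treatment, .data$replicate
  ))
}

#' All three stage transition tables of a dataset
#'
#' Convenience wrapper calling [replicate_proportions()] for predation
#' survival, emergence and seedling survival and row-binding the results into
#' the single long table the simulator consumes.
#'
#' @inheritParams replicate_proportions
#' @return A `transition_table` covering all three stages.
#' @export
transition_tables <- function(dataset) {
  new_transition_table(dplyr::bind_rows(
    replicate_proportions(dataset, "PREDATION_SURVIVAL"),
    replicate_proportions(dataset, "EMERGENCE"),
    replicate_proportions(dataset, "SEEDLING_SURVIVAL")
  ))
}

new_dispersal_distribution <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("microhabitat", "prob"), "dispersal distribution")
  if (any(x$prob < 0)) abort_validation("Deposition probabilities must be >= 0.")
  if (abs(sum(x$prob) - 1) > 1e-9) {
    abort_validation("Deposition probabilities must sum to 1 (tolerance 1e-9).")
  }
  structure(x, class = c("dispersal_distribution", class(tibble())))
}

#' Estimate where lizard-dispersed seeds are deposited
#'
#' Stage 1 of the seed-fate model: the probability that a gut-passed seed is
#' deposited in each microhabitat. Two sources are supported: the faeces
#' survey (`source = "faeces"`, the default — droppings containing target
#' seeds are the realized seed shadow) and direct microhabitat-use
#' observations of the disperser (`source = "use"` — time spent in a
#' microhabitat is taken as proportional to deposition there). Counts are
#' renormalized over `restrict_to`.
#'
#' @param dataset A [field_dataset()], or a tibble with `microhabitat` plus a
#'   `count` column (faeces-style input).
#' @param source `"faeces"` or `"use"`.
#' @param restrict_to Microhabitats over which to renormalize; defaults to the
#'   three studied microhabitats. Seeds recorded elsewhere are excluded before
#'   renormalization.
#' @return A `dispersal_distribution` tibble (`microhabitat`, `prob`), summing
#'   to 1.
#' @export
#' @examples
#' faeces <- tibble::tibble(
#'   microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
#'   count = c(70, 20, 10)
#' )
#' estimate_dispersal_distribution(faeces)
estimate_dispersal_distribution <- function(dataset,
                                            source = c("faeces", "use"),
                                            restrict_to = c("OPEN", "EPHEDRA", "PISTACIA")) {
  source <- match.arg(source)
  restrict_to <- canon_label(restrict_to)
  check_known_microhabitat(restrict_to, context = "restrict_to")
  counts <- if (inherits(dataset, "field_dataset")) {
    if (source == "faeces") {
      dataset$faeces
    } else {
      dataset$use_observations |>
        dplyr::count(.data$microhabitat, name = "count")
    }
  } else {
    as_tibble(dataset)
  }
  require_columns(counts, c("microhabitat", "count"), "deposition counts")
  counts <- counts |>
    dplyr::mutate(microhabitat = canon_label(.data$microhabitat)) |>
    dplyr::group_by(.data$microhabitat) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$microhabitat %in% restrict_to)
  total <- sum(counts$count)
  if (!isTRUE(total > 0)) {
    abort_estimation(sprintf(
      "Zero total deposition count within {%s}; cannot estimate a distribution.",
      paste(restrict_to, collapse = ", ")
    ))
  }
  out <- tibble(microhabitat = restrict_to) |>
    dplyr::left_join(counts, by = "microhabitat") |>
    dplyr::mutate(prob = dplyr::coalesce(.data$count, 0L) / total) |>
    dplyr::select("microhabitat", "prob")
  new_dispersal_distribution(out)
}

#' Microhabitat selection for seed deposition
#'
#' Compares the percentage of droppings deposited in each microhabitat with
#' its percentage cover. Equal percentages mean deposition is random with
#' respect to availability; a higher percentage of droppings than of cover
#' means positive selection of that microhabitat, a lower one negative
#' selection. Uncertainty comes from a multinomial bootstrap of the dropping
#' counts at the observed total (cover is held fixed); a microhabitat is
#' called positively selected when the lower bootstrap bound of the index
#' exceeds 0, negatively when the upper bound is below 0.
#'
#' @param faeces A [field_dataset()] or a tibble with `microhabitat` and
#'   `count`.
#' @param cover A [cover_table()]; taken from the dataset when `faeces` is a
#'   `field_dataset` and `cover` is `NULL`.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Two-sided interval coverage (default 0.95).
#' @return A `selection_index` tibble with one row per microhabitat:
#'   `droppings_pct`, `cover_pct`, `index` (percentage points,
#'   `droppings_pct - cover_pct`), `ci_low`, `ci_high` and `selection`
#'   (`"positive"`, `"negative"` or `"none"`).
#' @export
#' @examples
#' ds <- read_field_dataset(
#'   system.file("extdata", "dragonera_synthetic", package = "seedfate")
#' )
#' microhabitat_selection(ds, n_boot = 500, seed = 1)
microhabitat_selection <- function(faeces, cover = NULL, n_boot = 2000,
                                   seed = NULL, conf = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  if (inherits(faeces, "field_dataset")) {
    cover <- cover %||% faeces$cover
    faeces <- faeces$faeces
  }
  if (is.null(cover)) abort_config("`cover` is required.")
  cover <- validate_cover_table(cover)
  faeces <- as_tibble(faeces)
  require_columns(faeces, c("microhabitat", "count"), "faeces")
  faeces <- faeces |>
    dplyr::mutate(microhabitat = canon_label(.data$microhabitat)) |>
    dplyr::group_by(.data$microhabitat) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  check_known_microhabitat(faeces$microhabitat, cover$microhabitat, "faeces")
  total <- sum(faeces$count)
  if (!isTRUE(total > 0)) abort_estimation("Faeces survey total must be > 0.")

  mh <- faeces$microhabitat
  counts <- faeces$count
  cover_pct <- cover$cover[match(mh, cover$microhabitat)] * 100
  droppings_pct <- 100 * counts / total
  index <- droppings_pct - cover_pct

  boot <- with_seed_if(seed, {
    draws <- rmultinom(n_boot, size = total, prob = counts / total)
    100 * draws / total - cover_pct   # index per resample, mh x n_boot
  })
  ci <- apply(boot, 1, quantile, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
              names = FALSE)
  out <- tibble(
    microhabitat = mh,
    droppings_pct = droppings_pct,
    cover_pct = cover_pct,
    index = index,
    ci_low = ci[1, ],
    ci_high = ci[2, ],
    selection = dplyr::case_when(
      ci[1, ] > 0 ~ "positive",
      ci[2, ] < 0 ~ "negative",
      TRUE ~ "none"
    )
  )
  structure(out, class = c("selection_index", class(tibble())),
            n_boot = n_boot, conf = conf)
}

#' Permutation comparison of two sets of replicate proportions
#'
#' A two-sided test of the difference in mean replicate-level proportions
#' between two groups, by permutation of group labels. Used in place of
#' model-based contrasts for tray/station designs. With `exact = TRUE` (the
#' default when the number of distinct label assignments is at most
#' `exact_limit`) all \eqn{\binom{n_a+n_b}{n_a}} assignments are enumerated
#' and the p-value is the exact fraction of assignments whose absolute mean
#' difference is at least the observed one. Otherwise `n_perm` random
#' permutations are drawn and the p-value is `(1 + b) / (1 + n_perm)`.
#'
#' @param group_a,group_b Numeric vectors of replicate proportions in
#'   `[0, 1]`.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` decides by `exact_limit`.
#' @param exact_limit Largest number of assignments enumerated exhaustively.
#' @return A one-row tibble: `estimate` (mean(a) - mean(b)), `p_value`,
#'   `method` and `n_resamples`.
#' @export
#' @examples
#' compare_proportions(c(1, 1, 1), c(0, 0, 0))  # exact p = 0.1
compare_proportions <- function(group_a, group_b, n_perm = 999, seed = NULL,
                                exact = NULL, exact_limit = 20000) {
  n_perm <- check_count(n_perm, "n_perm")
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort_validation("Both groups must be non-empty.")
  }
  check_probability(group_a, "group_a")
  check_probability(group_b, "group_b")
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pooled)
  obs <- mean(group_a) - mean(group_b)
  n_assign <- choose(n, na)
  use_exact <- exact %||% (n_assign <= exact_limit)
  eps <- 1e-12

  if (use_exact) {
    idx <- combn(n, na)
    diffs <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(abs(diffs) >= abs(obs) - eps)
    method <- "exact permutation (exhaustive enumeration)"
    n_res <- ncol(idx)
  } else {
    perm <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) {
        take <- sample.int(n, na)
        mean(pooled[take]) - mean(pooled[-take])
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(obs) - eps)) / (1 + n_perm)
    method <- "Monte Carlo permutation"
    n_res <- n_perm
  }
  tibble(estimate = obs, p_value = p, method = method, n_resamples = n_res)
}

#' Step-down sequential Bonferroni (Holm) adjustment
#'
#' Adjusts a vector of p-values by the Holm step-down procedure: sort
#' ascending, multiply the i-th smallest by (m - i + 1), enforce monotone
#' non-decreasing adjusted values, cap at 1, and restore the input order. The
#' computation is delegated to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "holm")
}
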