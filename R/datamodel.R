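#' Build a microhabitat cover table
#'
#' A cover table gives the fraction of the ground surface occupied by each
#' microhabitat. The three studied microhabitats (`OPEN`, `EPHEDRA`,
#' `PISTACIA`) must always be present; `OTHER` aggregates the remaining
#' vegetation and, when `other = NULL`, is filled in as the remainder to 1.
#'
#' @param open,ephedra,pistacia Cover fractions in `[0, 1]`.
#' @param other Cover fraction for the aggregated remaining vegetation, or
#'   `NULL` (default) to use `1 - open - ephedra - pistacia`.
#' @return A tibble with columns `microhabitat` and `cover`, of class
#'   `cover_table`.
#' @seealso [paper_cover_table()] for the packaged study-site values.
#' @export
#' @examples
#' cover_table(open = 0.5, ephedra = 0.2, pistacia = 0.2)
cover_table <- function(open, ephedra, pistacia, other = NULL) {
  named <- c(OPEN = open, EPHEDRA = ephedra, PISTACIA = pistacia)
  check_probability(named, "cover")
  if (is.null(other)) {
    other <- 1 - sum(named)
    if (other < -1e-9) {
      abort_validation("Named covers exceed 1; cannot infer `other` as remainder.")
    }
    other <- max(other, 0)
  }
  out <- tibble(
    microhabitat = microhabitat_levels(),
    cover = c(unname(named), other)
  )
  validate_cover_table(out)
}

validate_cover_table <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("microhabitat", "cover"), "cover table")
  x$microhabitat <- canon_label(x$microhabitat)
  check_known_microhabitat(x$microhabitat, context = "cover table")
  if (anyDuplicated(x$microhabitat)) {
    abort_validation("Duplicated microhabitat labels in cover table.")
  }
  missing <- setdiff(c("OPEN", "EPHEDRA", "PISTACIA"), x$microhabitat)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "Cover table must contain OPEN, EPHEDRA and PISTACIA; missing %s.",
      paste(missing, collapse = ", ")
    ))
  }
  check_probability(x$cover, "cover")
  total <- sum(x$cover)
  if (total <= 0 || total > 1 + 1e-6) {
    abort_validation(sprintf(
      "Covers must sum to a value in (0, 1]; they sum to %.6f.", total
    ))
  }
  structure(x, class = c("cover_table", class(tibble())))
}

#' Study-site cover table
#'
#' The percentage covers measured along 150 m of transects at the study site:
#' open ground 45.1%, *Pistacia lentiscus* 27.0%, *Ephedra fragilis* 17.5%,
#' with `OTHER` taken as the remainder (10.4%, covering the minor shrubs).
#'
#' @return A [cover_table()].
#' @export
#' @examples
#' paper_cover_table()
paper_cover_table <- function() {
  cover_table(open = 0.451, ephedra = 0.175, pistacia = 0.270)
}

require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "Missing column(s) %s in %s.",
      paste0("'", missing, "'", collapse = ", "), what
    ))
  }
  invisible(x)
}

#' Assemble a field dataset
#'
#' Bundles the five field-style tables of a seed-fate study into a single
#' validated object:
#'
#' * `cover`: a [cover_table()];
#' * `use_observations`: one row per lizard sighting
#'   (`microhabitat`, `zone`, `transect`);
#' * `faeces`: dropping-survey counts per microhabitat
#'   (`microhabitat`, `count`);
#' * `predation`: seed-predation trays (`tray_id`, `microhabitat`, `zone`,
#'   `set_id`, `n_exposed`, `n_surviving`, `censored`); censored (destroyed)
#'   trays are retained with `n_surviving = NA` and flagged, and are excluded
#'   only at estimation time;
#' * `sowing`: sowing stations by treatment (`station_id`, `microhabitat`,
#'   `zone`, `set_id`, `treatment`, `n_sown`, `n_emerged`, `n_surviving`).
#'
#' Extra columns (e.g. per-visit census counts) are carried through untouched;
#' only the final-census columns above feed the model.
#'
#' @param cover,use_observations,faeces,predation,sowing Data frames as
#'   described above.
#' @return A validated `field_dataset` object (a named list of tibbles).
#' @seealso [read_field_dataset()], [generate_field_dataset()]
#' @export
field_dataset <- function(cover, use_observations, faeces, predation, sowing) {
  validate_field_dataset(structure(
    list(
      cover = as_tibble(cover),
      use_observations = as_tibble(use_observations),
      faeces = as_tibble(faeces),
      predation = as_tibble(predation),
      sowing = as_tibble(sowing)
    ),
    class = "field_dataset"
  ))
}

#' Validate a field dataset
#'
#' Checks every invariant of the data model: known, cross-referenced
#' microhabitat labels; consistent zone labels; non-negative counts;
#' `n_surviving <= n_exposed` for trays and
#' `n_surviving <= n_emerged <= n_sown` for stations. Errors name the
#' offending record.
#'
#' @param x A `field_dataset` (or plain list with the same elements).
#' @return The validated `field_dataset`, with labels canonicalized to
#'   upper case, invisibly usable in pipelines.
#' @export
validate_field_dataset <- function(x) {
  needed <- c("cover", "use_observations", "faeces", "predation", "sowing")
  if (!is.list(x) || !all(needed %in% names(x))) {
    abort_validation(sprintf(
      "A field dataset needs elements %s.", paste(needed, collapse = ", ")
    ))
  }
  x$cover <- validate_cover_table(x$cover)
  known <- x$cover$microhabitat

  use <- as_tibble(x$use_observations)
  require_columns(use, c("microhabitat", "zone", "transect"), "use_observations")
  use$microhabitat <- canon_label(use$microhabitat)
  use$zone <- canon_label(use$zone)
  use$transect <- as.character(use$transect)
  check_known_microhabitat(use$microhabitat, known, "use_observations")

  faeces <- as_tibble(x$faeces)
  require_columns(faeces, c("microhabitat", "count"), "faeces")
  faeces$microhabitat <- canon_label(faeces$microhabitat)
  check_known_microhabitat(faeces$microhabitat, known, "faeces")
  if (anyDuplicated(faeces$microhabitat)) {
    abort_validation("Duplicated microhabitat rows in faeces survey.")
  }
  if (any(!is.finite(faeces$count)) || any(faeces$count < 0) ||
      any(faeces$count != round(faeces$count))) {
    abort_validation("Faeces counts must be non-negative integers.")
  }
  faeces$count <- as.integer(faeces$count)

  pred <- as_tibble(x$predation)
  require_columns(
    pred,
    c("tray_id", "microhabitat", "zone", "set_id", "n_exposed",
      "n_surviving", "censored"),
    "predation"
  )
  pred$tray_id <- as.character(pred$tray_id)
  pred$set_id <- as.character(pred$set_id)
  pred$microhabitat <- canon_label(pred$microhabitat)
  pred$zone <- canon_label(pred$zone)
  pred$censored <- as.logical(pred$censored)
  check_integerish(pred$n_exposed, "predation n_exposed")
  check_integerish(pred$n_surviving, "predation n_surviving")
  pred$n_exposed <- as.integer(pred$n_exposed)
  pred$n_surviving <- as.integer(pred$n_surviving)
  check_known_microhabitat(pred$microhabitat, known, "predation")
  if (anyDuplicated(pred$tray_id)) {
    abort_validation(sprintf(
      "Duplicated tray_id '%s' in predation table.",
      pred$tray_id[duplicated(pred$tray_id)][1]
    ))
  }
  if (any(is.na(pred$censored))) {
    abort_validation("Predation `censored` flags must be true/false, not missing.")
  }
  if (any(!is.finite(pred$n_exposed) | pred$n_exposed < 1)) {
    bad <- pred$tray_id[!is.finite(pred$n_exposed) | pred$n_exposed < 1][1]
    abort_validation(sprintf("Tray '%s': n_exposed must be a positive integer.", bad))
  }
  active <- !pred$censored
  bad <- active & (is.na(pred$n_surviving) | pred$n_surviving < 0 |
                     pred$n_surviving > pred$n_exposed)
  if (any(bad)) {
    abort_validation(sprintf(
      "Tray '%s': need 0 <= n_surviving <= n_exposed on non-censored trays.",
      pred$tray_id[bad][1]
    ))
  }

  sow <- as_tibble(x$sowing)
  require_columns(
    sow,
    c("station_id", "microhabitat", "zone", "set_id", "treatment",
      "n_sown", "n_emerged", "n_surviving"),
    "sowing"
  )
  sow$station_id <- as.character(sow$station_id)
  sow$set_id <- as.character(sow$set_id)
  sow$microhabitat <- canon_label(sow$microhabitat)
  sow$zone <- canon_label(sow$zone)
  sow$treatment <- canon_label(sow$treatment)
  check_integerish(sow$n_sown, "sowing n_sown")
  check_integerish(sow$n_emerged, "sowing n_emerged")
  check_integerish(sow$n_surviving, "sowing n_surviving")
  sow$n_sown <- as.integer(sow$n_sown)
  sow$n_emerged <- as.integer(sow$n_emerged)
  sow$n_surviving <- as.integer(sow$n_surviving)
  check_known_microhabitat(sow$microhabitat, known, "sowing")
  bad_trt <- setdiff(unique(sow$treatment), treatment_levels())
  if (length(bad_trt) > 0) {
    abort_validation(sprintf(
      "Unknown treatment label(s) %s in sowing; expected %s.",
      paste0("'", bad_trt, "'", collapse = ", "),
      paste(treatment_levels(), collapse = ", ")
    ))
  }
  if (nrow(sow) > 0) {
    key <- paste(sow$station_id, sow$treatment)
    if (anyDuplicated(key)) {
      abort_validation(sprintf(
        "Duplicated station/treatment pair '%s' in sowing table.",
        key[duplicated(key)][1]
      ))
    }
    ok <- is.finite(sow$n_sown) & sow$n_sown >= 1 &
      is.finite(sow$n_emerged) & is.finite(sow$n_surviving) &
      sow$n_surviving >= 0 & sow$n_surviving <= sow$n_emerged &
      sow$n_emerged <= sow$n_sown
    if (any(!ok)) {
      abort_validation(sprintf(
        "Station '%s' (%s): need 0 <= n_surviving <= n_emerged <= n_sown.",
        sow$station_id[!ok][1], sow$treatment[!ok][1]
      ))
    }
  }

  zones <- unique(c(pred$zone, sow$zone, use$zone))
  zones <- zones[!is.na(zones)]
  if (length(zones) > 0 && length(unique(zones)) > 26) {
    abort_validation("Implausible number of distinct zone labels.")
  }

  structure(
    list(cover = x$cover, use_observations = use, faeces = faeces,
         predation = pred, sowing = sow),
    class = "field_dataset"
  )
}

#' @export
print.field_dataset <- function(x, ...) {
  n_cens <- sum(x$predation$censored)
  cat("<field_dataset>\n")
  cat(sprintf("  cover:            %d microhabitats (sum %.3f)\n",
              nrow(x$cover), sum(x$cover$cover)))
  cat(sprintf("  use_observations: %d sightings\n", nrow(x$use_observations)))
  cat(sprintf("  faeces:           %d droppings over %d microhabitats\n",
              sum(x$faeces$count), nrow(x$faeces)))
  cat(sprintf("  predation:        %d trays (%d censored)\n",
              nrow(x$predation), n_cens))
  cat(sprintf("  sowing:           %d station x treatment records\n",
              nrow(x$sowing)))
  invisible(x)
}
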