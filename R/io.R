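dataset_files <- c(
  cover = "cover.csv",
  use_observations = "use_observations.csv",
  faeces = "faeces.csv",
  predation = "predation.csv",
  sowing = "sowing.csv"
)

read_table_csv <- function(path, what) {
  if (!file.exists(path)) {
    abort_io(sprintf("File for %s table not found: '%s'.", what, path))
  }
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_io(sprintf("Failed to read '%s': %s", path, conditionMessage(e)))
  )
  as_tibble(out)
}

#' Read a field dataset from delimited text files
#'
#' Reads the five comma-separated tables of a field dataset (each with a
#' mandatory header row) and validates them as a whole. Microhabitat, zone and
#' treatment labels are case-insensitive on read and canonicalized to upper
#' case. Censored predation trays are retained and flagged, never dropped.
#'
#' @param dir Directory containing `cover.csv`, `use_observations.csv`,
#'   `faeces.csv`, `predation.csv` and `sowing.csv`.
#' @param paths Optional named character vector overriding individual file
#'   paths (names among `cover`, `use_observations`, `faeces`, `predation`,
#'   `sowing`).
#' @return A validated [field_dataset()].
#' @seealso [write_field_dataset()] for the inverse;
#'   `system.file("extdata", "dragonera_synthetic", package = "seedfate")`
#'   for a packaged example dataset.
#' @export
#' @examples
#' path <- system.file("extdata", "dragonera_synthetic", package = "seedfate")
#' ds <- read_field_dataset(path)
#' ds
read_field_dataset <- function(dir = NULL, paths = NULL) {
  files <- dataset_files
  if (!is.null(dir)) files <- setNames(file.path(dir, files), names(files))
  if (!is.null(paths)) files[names(paths)] <- paths
  tabs <- lapply(names(files), function(nm) read_table_csv(files[[nm]], nm))
  names(tabs) <- names(files)
  # readr may parse an all-"true"/"false" column as character; coerce here.
  if ("censored" %in% names(tabs$predation)) {
    tabs$predation$censored <- parse_bool(tabs$predation$censored, "censored")
  }
  validate_field_dataset(tabs)
}

parse_bool <- function(x, name) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- ifelse(lx %in% c("true", "t", "1"), TRUE,
                ifelse(lx %in% c("false", "f", "0"), FALSE, NA))
  if (any(is.na(out) & !is.na(x))) {
    abort_validation(sprintf("Column '%s' contains non-boolean values.", name))
  }
  out
}

#' Write a field dataset to delimited text files
#'
#' Writes the five tables of a [field_dataset()] as comma-separated files with
#' header rows into `dir` (created if needed). Logical flags are written as
#' lower-case `true`/`false`. The round trip
#' `read_field_dataset(write_field_dataset(x, dir))` reproduces `x`
#' field-for-field.
#'
#' @param dataset A validated [field_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_field_dataset <- function(dataset, dir) {
  dataset <- validate_field_dataset(dataset)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("Cannot create directory '%s'.", dir))
  }
  tabs <- dataset
  tabs$predation$censored <- tolower(as.character(tabs$predation$censored))
  for (nm in names(dataset_files)) {
    path <- file.path(dir, dataset_files[[nm]])
    tryCatch(
      readr::write_csv(as_tibble(tabs[[nm]]), path, progress = FALSE),
      error = function(e) abort_io(sprintf("Failed to write '%s': %s", path, conditionMessage(e)))
    )
  }
  invisible(dir)
}

#' Export or import a field dataset as a single JSON file
#'
#' A JSON representation of all five tables for single-file exchange.
#'
#' @param dataset A validated [field_dataset()].
#' @param path File path for the JSON document.
#' @return `write_field_dataset_json()` returns `path` invisibly;
#'   `read_field_dataset_json()` returns a validated [field_dataset()].
#' @export
write_field_dataset_json <- function(dataset, path) {
  dataset <- validate_field_dataset(dataset)
  jsonlite::write_json(unclass(dataset), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_field_dataset_json
#' @export
read_field_dataset_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: '%s'.", path))
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort_io(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)))
  )
  raw <- lapply(raw, as_tibble)
  if (nrow(raw$predation) > 0 && !is.logical(raw$predation$censored)) {
    raw$predation$censored <- parse_bool(raw$predation$censored, "censored")
  }
  validate_field_dataset(raw)
}
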