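# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish validation, estimation, simulation, configuration and I/O
# failures without string-matching messages.

abort_validation <- function(message, ...) {
  abort(message, class = c("seedfate_validation_error", "seedfate_error"), ...)
}

abort_estimation <- function(message, ...) {
  abort(message, class = c("seedfate_estimation_error", "seedfate_error"), ...)
}

abort_simulation <- function(message, ...) {
  abort(message, class = c("seedfate_simulation_error", "seedfate_error"), ...)
}

abort_config <- function(message, ...) {
  abort(message, class = c("seedfate_config_error", "seedfate_error"), ...)
}

abort_io <- function(message, ...) {
  abort(message, class = c("seedfate_io_error", "seedfate_error"), ...)
}

# Canonicalize a microhabitat/treatment/zone label: trim, upper-case.
canon_label <- function(x) toupper(trimws(as.character(x)))

check_known_microhabitat <- function(x, known = microhabitat_levels(),
                                     context = "record") {
  bad <- setdiff(unique(x[!is.na(x)]), known)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Unknown microhabitat label(s) %s in %s; expected one of %s.",
      paste0("'", bad, "'", collapse = ", "), context,
      paste(known, collapse = ", ")
    ))
  }
  invisible(x)
}

check_probability <- function(x, name, tol = 0) {
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol)) {
    abort_validation(sprintf(
      "`%s` must be in [0, 1]; got %s.", name,
      paste(format(x[!is.finite(x) | x < -tol | x > 1 + tol]), collapse = ", ")
    ))
  }
  invisible(x)
}

check_integerish <- function(x, name) {
  x <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & (!is.finite(x) | x != round(x))
  if (any(bad)) {
    abort_validation(sprintf("Column %s must contain whole numbers.", name))
  }
  invisible(x)
}

check_count <- function(n, name, min = 1L) {
  if (length(n) != 1 || !is.finite(n) || n != as.integer(n) || n < min) {
    abort_config(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(n))
}

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; with seed = NULL the global stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    seed <- check_count(seed, "seed", min = -.Machine$integer.max)
    withr::with_seed(seed, expr)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
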