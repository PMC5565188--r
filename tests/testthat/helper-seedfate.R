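# Builders for small in-code fixtures.

# A transition table from a compact list spec:
#   groups = list(list(stage=, microhabitat=, treatment=, props=), ...)
make_tables <- function(groups) {
  purrr::map_dfr(groups, function(g) {
    tibble::tibble(
      stage = g$stage,
      microhabitat = g$microhabitat,
      treatment = g$treatment %||% NA_character_,
      replicate = paste0("r", seq_along(g$props)),
      proportion = g$props
    )
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Full three-stage tables where every needed group is a single replicate,
# so the simulation is deterministic.
constant_tables <- function(s2 = 0.5, s3 = 0.5, s4 = 0.5,
                            microhabitats = c("OPEN", "EPHEDRA", "PISTACIA"),
                            treatments = c("DIGESTED", "RED", "YELLOW")) {
  groups <- list()
  for (m in microhabitats) {
    groups <- c(groups, list(list(
      stage = "PREDATION_SURVIVAL", microhabitat = m, props = s2
    )))
    for (t in treatments) {
      groups <- c(groups, list(
        list(stage = "EMERGENCE", microhabitat = m, treatment = t, props = s3),
        list(stage = "SEEDLING_SURVIVAL", microhabitat = m, treatment = t,
             props = s4)
      ))
    }
  }
  make_tables(groups)
}

# Randomized small tables (2-5 replicates per group) for property tests.
random_tables <- function(seed) {
  withr::with_seed(seed, {
    groups <- list()
    for (m in c("OPEN", "EPHEDRA", "PISTACIA")) {
      groups <- c(groups, list(list(
        stage = "PREDATION_SURVIVAL", microhabitat = m,
        props = stats::runif(sample(2:5, 1))
      )))
      for (t in c("DIGESTED", "RED", "YELLOW")) {
        groups <- c(groups, list(
          list(stage = "EMERGENCE", microhabitat = m, treatment = t,
               props = stats::runif(sample(2:5, 1))),
          list(stage = "SEEDLING_SURVIVAL", microhabitat = m, treatment = t,
               props = stats::runif(sample(2:5, 1)))
        ))
      }
    }
    make_tables(groups)
  })
}

random_dispersal <- function(seed) {
  withr::with_seed(seed, {
    p <- stats::runif(3)
    tibble::tibble(
      microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
      prob = p / sum(p)
    )
  })
}

uniform_dispersal <- function() {
  tibble::tibble(
    microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
    prob = rep(1 / 3, 3)
  )
}

point_dispersal <- function(microhabitat) {
  tibble::tibble(microhabitat = microhabitat, prob = 1)
}

within_list <- function(x, name, value) {
  x[[name]] <- value
  x
}

# A minimal valid field dataset built by hand.
tiny_dataset <- function() {
  field_dataset(
    cover = paper_cover_table(),
    use_observations = tibble::tibble(
      microhabitat = c("OPEN", "OPEN", "PISTACIA"),
      zone = c("A", "B", "A"),
      transect = c("TR1", "TR2", "TR1")
    ),
    faeces = tibble::tibble(
      microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
      count = c(70, 20, 10)
    ),
    predation = tibble::tibble(
      tray_id = c("T01", "T02", "T03", "T04"),
      microhabitat = c("OPEN", "OPEN", "EPHEDRA", "PISTACIA"),
      zone = c("A", "A", "B", "B"),
      set_id = c("S1", "S2", "S1", "S1"),
      n_exposed = 10L,
      n_surviving = c(4L, 6L, 0L, 2L),
      censored = FALSE
    ),
    sowing = tidyr::expand_grid(
      station_id = c("E01", "E02"),
      treatment = c("DIGESTED", "RED", "YELLOW")
    ) |>
      dplyr::mutate(
        microhabitat = ifelse(station_id == "E01", "OPEN", "EPHEDRA"),
        zone = "A", set_id = "S1",
        n_sown = 10L, n_emerged = 5L, n_surviving = 1L
      )
  )
}
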