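test_that("replicate proportions follow the stage definitions", {
  ds <- tiny_dataset()
  tt <- replicate_proportions(ds, "PREDATION_SURVIVAL")
  open <- sort(tt$proportion[tt$microhabitat == "OPEN"])
  expect_equal(open, c(0.4, 0.6))
  expect_true(all(is.na(tt$treatment)))

  # emergence uses n_emerged / n_sown per station x treatment
  em <- replicate_proportions(ds, "EMERGENCE")
  expect_equal(unique(em$proportion), 0.5)
  expect_equal(nrow(em), 6)

  # seedling survival is conditional on emergence
  sv <- replicate_proportions(ds, "SEEDLING_SURVIVAL")
  expect_equal(unique(sv$proportion), 1 / 5)
})

test_that("censored trays are excluded but zero survivors still count", {
  pred <- tibble::tibble(
    tray_id = c("T10", "T11"),
    microhabitat = "EPHEDRA", zone = "A", set_id = "S1",
    n_exposed = 10L, n_surviving = c(NA, 0L), censored = c(TRUE, FALSE)
  )
  tt <- replicate_proportions(pred, "PREDATION_SURVIVAL")
  expect_equal(tt$proportion, 0)
  expect_equal(tt$replicate, "T11")

  all_censored <- dplyr::mutate(pred, censored = TRUE, n_surviving = NA)
  expect_error(replicate_proportions(all_censored, "PREDATION_SURVIVAL"),
               "EPHEDRA", class = "seedfate_estimation_error")
})

test_that("zero-emergence stations contribute no seedling-survival replicate", {
  sow <- tibble::tibble(
    station_id = c("E1", "E2"), microhabitat = "OPEN", zone = "A",
    set_id = "S1", treatment = "DIGESTED",
    n_sown = 10L, n_emerged = c(0L, 4L), n_surviving = c(0L, 1L)
  )
  tt <- replicate_proportions(sow, "SEEDLING_SURVIVAL")
  expect_equal(tt$replicate, "E2")
  expect_equal(tt$proportion, 0.25)

  none <- dplyr::mutate(sow, n_emerged = 0L, n_surviving = 0L)
  expect_error(replicate_proportions(none, "SEEDLING_SURVIVAL"),
               "OPEN/DIGESTED", class = "seedfate_estimation_error")
})

test_that("replicate_proportions is invariant to record order", {
  ds <- generate_field_dataset(paper_like_truth(), paper_design(), seed = 5)
  shuffled <- ds
  withr::with_seed(1, {
    shuffled$predation <- shuffled$predation[sample(nrow(shuffled$predation)), ]
    shuffled$sowing <- shuffled$sowing[sample(nrow(shuffled$sowing)), ]
  })
  expect_equal(transition_tables(shuffled), transition_tables(ds))
})

test_that("dispersal distributions are renormalized counts", {
  f <- tibble::tibble(microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
                      count = c(70, 20, 10))
  d <- estimate_dispersal_distribution(f)
  expect_equal(setNames(d$prob, d$microhabitat),
               c(OPEN = 0.7, EPHEDRA = 0.2, PISTACIA = 0.1))

  one <- estimate_dispersal_distribution(
    tibble::tibble(microhabitat = "OPEN", count = 140),
    restrict_to = "OPEN"
  )
  expect_equal(one$prob, 1)

  # renormalization over a restricted set drops OTHER's 20 droppings
  four <- tibble::tibble(
    microhabitat = c("OPEN", "EPHEDRA", "PISTACIA", "OTHER"),
    count = c(50, 25, 25, 20)
  )
  d4 <- estimate_dispersal_distribution(four)
  expect_equal(setNames(d4$prob, d4$microhabitat),
               c(OPEN = 0.5, EPHEDRA = 0.25, PISTACIA = 0.25))
  expect_equal(sum(d4$prob), 1, tolerance = 1e-12)

  empty <- tibble::tibble(microhabitat = "OTHER", count = 5)
  expect_error(estimate_dispersal_distribution(empty),
               class = "seedfate_estimation_error")
})

test_that("use-based and faeces-based dispersal sources both work", {
  ds <- tiny_dataset()
  by_faeces <- estimate_dispersal_distribution(ds, source = "faeces")
  by_use <- estimate_dispersal_distribution(ds, source = "use")
  expect_equal(sum(by_use$prob), 1, tolerance = 1e-12)
  # tiny_dataset has 2 OPEN + 1 PISTACIA sightings
  expect_equal(by_use$prob[by_use$microhabitat == "OPEN"], 2 / 3)
  expect_false(isTRUE(all.equal(by_faeces$prob, by_use$prob)))
})

test_that("selection index is droppings percentage minus cover percentage", {
  all_open <- tibble::tibble(microhabitat = "OPEN", count = 140)
  sel <- microhabitat_selection(all_open, cover = paper_cover_table(),
                                n_boot = 50, seed = 1)
  expect_equal(sel$index[sel$microhabitat == "OPEN"], 100 - 45.1)
  expect_equal(sum(sel$droppings_pct), 100, tolerance = 1e-9)

  # droppings proportional to cover -> all indices 0
  ct <- paper_cover_table()
  prop <- tibble::tibble(microhabitat = ct$microhabitat,
                         count = ct$cover * 1000)
  sel0 <- microhabitat_selection(prop, cover = ct, n_boot = 50, seed = 1)
  expect_equal(sel0$index, rep(0, 4), tolerance = 1e-9)
})

test_that("a strongly selected microhabitat gets an interval excluding zero", {
  total <- 0.451 + 0.175 + 0.270
  ct <- cover_table(open = 0.451 / total, ephedra = 0.175 / total,
                    pistacia = 0.270 / total)
  counts <- tibble::tibble(microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
                           count = c(9000, 500, 500))
  sel <- microhabitat_selection(counts, cover = ct, n_boot = 2000, seed = 7)
  expect_gt(sel$ci_low[sel$microhabitat == "OPEN"], 0)
  expect_equal(sel$selection[sel$microhabitat == "OPEN"], "positive")
  expect_lt(sel$ci_high[sel$microhabitat == "EPHEDRA"], 0)
  # reproducible under the same seed
  sel2 <- microhabitat_selection(counts, cover = ct, n_boot = 2000, seed = 7)
  expect_equal(tidy(sel), tidy(sel2))
})

test_that("permutation comparison handles null, extreme and seeded cases", {
  same <- compare_proportions(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)

  extreme <- compare_proportions(c(1, 1, 1), c(0, 0, 0))
  expect_equal(extreme$p_value, 2 / choose(6, 3))
  expect_equal(extreme$p_value, 0.1)

  a <- c(0.1, 0.5, 0.9, 0.2, 0.8, 0.3, 0.6, 0.4)
  b <- c(0.2, 0.6, 0.7, 0.1, 0.9, 0.5, 0.35, 0.45)
  p1 <- compare_proportions(a, b, n_perm = 499, seed = 42, exact = FALSE)
  p2 <- compare_proportions(a, b, n_perm = 499, seed = 42, exact = FALSE)
  expect_identical(p1, p2)
  expect_true(p1$p_value > 0 && p1$p_value <= 1)

  expect_error(compare_proportions(numeric(0), c(0.5)),
               class = "seedfate_validation_error")
  expect_error(compare_proportions(c(0.5), c(0.5), n_perm = 0),
               class = "seedfate_config_error")
})

test_that("permutation p-values are near-uniform under an exchangeable null", {
  withr::with_seed(99, {
    p <- vapply(seq_len(200), function(i) {
      pool <- stats::runif(16)
      compare_proportions(pool[1:8], pool[9:16], n_perm = 999,
                          exact = FALSE)$p_value
    }, numeric(1))
  })
  # empirical CDF within Monte-Carlo error of uniform
  expect_lt(abs(mean(p) - 0.5), 0.07)
  expect_lt(abs(mean(p <= 0.1) - 0.1), 0.075)
  expect_lt(abs(mean(p <= 0.5) - 0.5), 0.12)
})

test_that("holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.5, 0.6)), c(1, 1))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.012)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))                      # never smaller than input
  expect_equal(min(adj), min(p) * length(p))      # smallest is Bonferroni
  expect_error(holm_adjust(c(0.5, 1.2)), class = "seedfate_validation_error")
})
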