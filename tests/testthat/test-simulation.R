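test_that("chain_product multiplies stage probabilities", {
  expect_equal(chain_product(1, 0.5, 0.5, 0.5),
               tibble::tibble(p_newly_emerged = 0.25, p_surviving = 0.125))
  # absorbing zeros
  expect_equal(chain_product(0, 1, 1, 1)$p_newly_emerged, 0)
  expect_equal(chain_product(1, 1, 1, 0)$p_surviving, 0)
  out <- chain_product(0.7, 0.057, 0.523, 0.085)
  expect_equal(out$p_newly_emerged, 0.7 * 0.057 * 0.523, tolerance = 1e-12)
  expect_equal(round(out$p_newly_emerged, 6), 0.020868)
  expect_equal(round(out$p_surviving, 6), 0.001774)
  expect_error(chain_product(1.2, 0.5, 0.5, 0.5),
               class = "seedfate_validation_error")
})

test_that("single-replicate groups make the simulation deterministic", {
  tabs <- constant_tables(s2 = 0.3, s3 = 0.4, s4 = 0.5)
  res <- run_seed_fate_simulation(
    tabs, uniform_dispersal(),
    config = simulation_config(n_iterations = 200, rng_seed = 1)
  )
  s <- res$summaries
  expect_equal(s$se, rep(0, nrow(s)))
  expect_equal(
    s$mean[s$pathway == "DISPERSED" & s$quantity == "p_newly_emerged"],
    0.3 * 0.4
  )
  expect_equal(
    s$mean[s$pathway == "DISPERSED" & s$quantity == "p_surviving"],
    0.3 * 0.4 * 0.5
  )
  # identical to the analytic expectation
  exp_out <- analytic_expected_outcome(tabs, uniform_dispersal())
  expect_equal(
    exp_out$p_newly_emerged[exp_out$pathway == "DISPERSED"], 0.12
  )
})

test_that("a fair pick between 0 and 1 converges to one half", {
  tabs <- constant_tables(s2 = 1, s3 = 1, s4 = 1)
  tabs$proportion[tabs$stage == "PREDATION_SURVIVAL" &
                    tabs$microhabitat == "OPEN"] <- 0
  tabs <- dplyr::bind_rows(tabs, tibble::tibble(
    stage = "PREDATION_SURVIVAL", microhabitat = "OPEN",
    treatment = NA_character_, replicate = "r2", proportion = 1
  ))
  n <- 20000
  res <- run_seed_fate_simulation(
    tabs, point_dispersal("OPEN"),
    config = simulation_config(n_iterations = n, rng_seed = 2)
  )
  m <- res$summaries$mean[res$summaries$pathway == "DISPERSED" &
                           res$summaries$quantity == "p_newly_emerged"]
  mc_se <- 0.5 / sqrt(n)  # sd of a fair 0/1 pick is 0.5
  expect_lt(abs(m - 0.5), 3 * mc_se)
})

test_that("zero seedling survival under the mother plant forces a zero pathway", {
  tabs <- random_tables(31)
  tabs$proportion[tabs$stage == "SEEDLING_SURVIVAL" &
                    tabs$microhabitat == "EPHEDRA"] <- 0
  res <- run_seed_fate_simulation(
    tabs, random_dispersal(31),
    config = simulation_config(n_iterations = 300, rng_seed = 3)
  )
  undisp <- res$iterations[res$iterations$pathway == "UNDISPERSED", ]
  expect_true(all(undisp$p_surviving == 0))
  adv <- dispersal_advantage(res)
  expect_identical(adv$ratio[adv$quantity == "p_surviving"], Inf)
})

test_that("analytic oracle equals group-mean chaining", {
  tabs <- make_tables(list(
    list(stage = "PREDATION_SURVIVAL", microhabitat = "OPEN",
         props = c(0.2, 0.4)),
    list(stage = "EMERGENCE", microhabitat = "OPEN", treatment = "DIGESTED",
         props = 0.5),
    list(stage = "SEEDLING_SURVIVAL", microhabitat = "OPEN",
         treatment = "DIGESTED", props = 1),
    # undispersed pathway groups (EPHEDRA), all 1 so they do not interfere
    list(stage = "PREDATION_SURVIVAL", microhabitat = "EPHEDRA", props = 1),
    list(stage = "EMERGENCE", microhabitat = "EPHEDRA", treatment = "RED",
         props = 1),
    list(stage = "EMERGENCE", microhabitat = "EPHEDRA", treatment = "YELLOW",
         props = 1),
    list(stage = "SEEDLING_SURVIVAL", microhabitat = "EPHEDRA",
         treatment = "RED", props = 0),
    list(stage = "SEEDLING_SURVIVAL", microhabitat = "EPHEDRA",
         treatment = "YELLOW", props = 0)
  ))
  out <- analytic_expected_outcome(tabs, point_dispersal("OPEN"))
  expect_equal(out$p_newly_emerged[out$pathway == "DISPERSED"], 0.3 * 0.5)
  # undispersed seedling survival mean 0 -> expected surviving 0
  expect_equal(out$p_surviving[out$pathway == "UNDISPERSED"], 0)
})

test_that("identical configuration and seed give bit-identical results", {
  tabs <- random_tables(7)
  disp <- random_dispersal(7)
  cfg <- simulation_config(n_iterations = 400, rng_seed = 99)
  r1 <- run_seed_fate_simulation(tabs, disp, config = cfg)
  r2 <- run_seed_fate_simulation(tabs, disp, config = cfg)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$summaries, r2$summaries)
})

test_that("every iteration is ordered and conserves probability mass", {
  for (seed in c(11, 12, 13)) {
    res <- run_seed_fate_simulation(
      random_tables(seed), random_dispersal(seed),
      config = simulation_config(n_iterations = 250, rng_seed = seed,
                                 iteration_draw_mode =
                                   if (seed %% 2) "single_replicate" else "resampled_mean")
    )
    it <- res$iterations
    expect_true(all(it$p_surviving <= it$p_newly_emerged + 1e-12))
    expect_true(all(it$p_newly_emerged <= it$p_predation_survival + 1e-12))
    expect_true(all(it$p_predation_survival <= 1))
    fr <- seed_fate_fractions(res, per_iteration = TRUE)
    total <- fr$predated + fr$ungerminated + fr$emerged_died + fr$surviving
    expect_true(all(abs(total - 1) < 1e-9))
  }
})

test_that("raising any stage group never decreases the expected outcome", {
  for (seed in c(21, 22, 23, 24)) {
    tabs <- random_tables(seed)
    disp <- random_dispersal(seed)
    base <- analytic_expected_outcome(tabs, disp)
    keys <- dplyr::distinct(tabs[c("stage", "microhabitat", "treatment")])
    pick <- keys[withr::with_seed(seed, sample(nrow(keys), 1)), ]
    bumped <- tabs
    sel <- bumped$stage == pick$stage &
      bumped$microhabitat == pick$microhabitat &
      (is.na(pick$treatment) & is.na(bumped$treatment) |
         !is.na(bumped$treatment) & bumped$treatment %in% pick$treatment)
    bumped$proportion[sel] <- pmin(1, bumped$proportion[sel] + 0.2)
    up <- analytic_expected_outcome(bumped, disp)
    expect_true(all(up$p_newly_emerged >= base$p_newly_emerged - 1e-12))
    expect_true(all(up$p_surviving >= base$p_surviving - 1e-12))
  }
})

test_that("cover weighting multiplies deposition by relative cover", {
  tabs <- constant_tables(s2 = 0.5, s3 = 0.5, s4 = 0.5)
  tabs$proportion[tabs$stage == "PREDATION_SURVIVAL" &
                    tabs$microhabitat == "OPEN"] <- 1
  disp <- tibble::tibble(microhabitat = c("OPEN", "EPHEDRA", "PISTACIA"),
                         prob = c(0.6, 0.2, 0.2))
  ct <- paper_cover_table()
  cfg <- simulation_config(n_iterations = 10, rng_seed = 1,
                           weighting_mode = "dispersal_times_cover")
  out <- analytic_expected_outcome(tabs, disp, cover = ct, config = cfg)
  w <- c(0.6 * 0.451, 0.2 * 0.175, 0.2 * 0.270)
  w <- w / sum(w)
  expected <- (w[1] * 1 + w[2] * 0.5 + w[3] * 0.5) * 0.5
  expect_equal(out$p_newly_emerged[out$pathway == "DISPERSED"], expected)
  expect_error(
    run_seed_fate_simulation(tabs, disp, cover = NULL, config = cfg),
    class = "seedfate_config_error"
  )
})

test_that("missing groups are reported by name before any draw", {
  tabs <- constant_tables(microhabitats = c("OPEN", "EPHEDRA"))
  disp <- random_dispersal(5)  # includes PISTACIA
  expect_error(
    run_seed_fate_simulation(tabs, disp,
                             config = simulation_config(n_iterations = 10)),
    "PISTACIA", class = "seedfate_simulation_error"
  )
})

test_that("stage losses decompose and flag undefined fractions", {
  tabs <- constant_tables(s2 = 0.057, s3 = 0.523, s4 = 0.085)
  res <- run_seed_fate_simulation(
    tabs, uniform_dispersal(),
    config = simulation_config(n_iterations = 50, rng_seed = 1)
  )
  losses <- stage_loss_decomposition(res)
  d <- losses[losses$pathway == "DISPERSED", ]
  expect_equal(d$conditional_loss[d$stage == "PREDATION"], 1 - 0.057)
  expect_equal(d$conditional_loss[d$stage == "EMERGENCE_FAILURE"], 1 - 0.523)
  expect_equal(d$conditional_loss[d$stage == "SEEDLING_MORTALITY"], 1 - 0.085)
  expect_equal(d$n_undefined, c(0L, 0L, 0L), ignore_attr = TRUE)

  # all survivals 1 -> all losses 0
  ones <- run_seed_fate_simulation(
    constant_tables(1, 1, 1), uniform_dispersal(),
    config = simulation_config(n_iterations = 20, rng_seed = 1)
  )
  expect_equal(stage_loss_decomposition(ones)$conditional_loss, rep(0, 6))

  # predation survival 0 -> downstream conditional fractions undefined
  dead <- run_seed_fate_simulation(
    constant_tables(0, 1, 1), uniform_dispersal(),
    config = simulation_config(n_iterations = 20, rng_seed = 1)
  )
  dl <- stage_loss_decomposition(dead)
  expect_equal(dl$conditional_loss[dl$stage == "PREDATION"], c(1, 1))
  expect_true(all(is.na(dl$conditional_loss[dl$stage != "PREDATION"])))
  expect_true(all(dl$n_undefined[dl$stage != "PREDATION"] == 20))
})

test_that("advantage ratios cover finite, unit, infinite and undefined cases", {
  mk <- function(d_newly, u_newly, d_surv = d_newly / 10,
                 u_surv = u_newly / 10) {
    structure(list(
      summaries = tibble::tibble(
        pathway = rep(c("DISPERSED", "UNDISPERSED"), each = 2),
        quantity = rep(c("p_newly_emerged", "p_surviving"), 2),
        mean = c(d_newly, d_surv, u_newly, u_surv),
        se = 0
      )
    ), class = "seed_fate_result")
  }
  adv <- dispersal_advantage(mk(0.030, 0.0025))
  expect_equal(adv$ratio[adv$quantity == "p_newly_emerged"], 12)
  expect_equal(dispersal_advantage(mk(0.2, 0.2))$ratio, c(1, 1))
  inf <- dispersal_advantage(mk(0.030, 0.0025, d_surv = 0.003, u_surv = 0))
  expect_identical(inf$ratio[inf$quantity == "p_surviving"], Inf)
  none <- dispersal_advantage(mk(0, 0, 0, 0))
  expect_true(all(is.na(none$ratio)))
})

test_that("tidiers summarize results consistently", {
  res <- run_seed_fate_simulation(
    random_tables(3), random_dispersal(3),
    config = simulation_config(n_iterations = 100, rng_seed = 4)
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("pathway", "quantity", "mean", "se"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  adv <- dispersal_advantage(res)
  expect_equal(gl$advantage_newly_emerged,
               adv$ratio[adv$quantity == "p_newly_emerged"])
})
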