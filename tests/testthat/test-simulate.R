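cfg <- default_config()

test_that("identical seeds give bit-identical simulations", {
  a <- run_trials(cfg, n_trials = 250, seed = 11)
  b <- run_trials(cfg, n_trials = 250, seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(summarize_simulation(a)$stats, summarize_simulation(b)$stats)
  c <- run_trials(cfg, n_trials = 250, seed = 12)
  expect_false(identical(a$trials, c$trials))
})

test_that("all-point inputs collapse the simulation to the static base case", {
  pc <- point_config(cfg)
  sim <- run_trials(pc, n_trials = 3, seed = 1)
  for (cat in c("sexual_assault", "other_crimes")) {
    static <- category_annual(cfg, cat, "base")
    got <- sim$trials[sim$trials$category == cat, ]
    expect_equal(unique(got$victims), static$victims)
    expect_equal(unique(got$tangible), static$tangible)
    expect_equal(unique(got$intangible), static$intangible)
    expect_equal(unique(got$investigation_cost), static$investigation_cost)
  }
  mc_murder <- sim$trials[sim$trials$category == "murder", ]
  static_murder <- murder_savings(cfg, "base")
  expect_equal(unique(mc_murder$victims),
               static_murder$victims[static_murder$scope == "annual"])
})

test_that("every sampled input lies within its stated support", {
  sim <- run_trials(cfg, n_trials = 500, seed = 3)
  for (i in seq_len(nrow(cfg$categories))) {
    row <- cfg$categories[i, ]
    col <- sim$trials[sim$trials$category == row$category, ][[row$parameter]]
    if (is.null(col) || all(is.na(col))) next # parameter not used by this variant
    expect_true(all(col >= row$low & col <= row$high),
                label = paste(row$category, row$parameter, "within support"))
  }
})

test_that("trial outcomes stay inside the all-endpoint static envelope", {
  for (variant in c("annual_uploads", "total_cases")) {
    sim <- run_trials(cfg, n_trials = 1000, seed = 5, variant = variant)
    env <- static_envelope(cfg, variant = variant)
    dat <- dplyr::bind_rows(
      sim$trials[c("trial", "category", "leads", "victims", "tangible",
                   "intangible", "investigation_cost")],
      dplyr::mutate(
        dplyr::summarise(
          dplyr::group_by(sim$trials, trial),
          dplyr::across(c(leads, victims, tangible, intangible, investigation_cost), sum),
          .groups = "drop"
        ),
        category = "combined"
      )
    )
    long <- tidyr::pivot_longer(dat, c(leads, victims, tangible, intangible,
                                       investigation_cost),
                                names_to = "outcome", values_to = "value")
    joined <- dplyr::left_join(long, env, by = c("category", "outcome"))
    tol <- 1e-9 * pmax(1, abs(joined$max))
    expect_true(all(joined$value >= joined$min - tol))
    expect_true(all(joined$value <= joined$max + tol))
  }
})

test_that("simulated means converge to the closed-form expectation oracle", {
  n <- 100000
  sim <- run_trials(cfg, n_trials = n, seed = 9)
  expected <- oracle_expectation(cfg)
  got <- dplyr::summarise(
    dplyr::group_by(sim$trials, category),
    victims_sd = sd(victims), tangible_sd = sd(tangible),
    victims = mean(victims), tangible = mean(tangible),
    .groups = "drop"
  )
  z <- c()
  for (cat in c("sexual_assault", "other_crimes", "murder")) {
    e <- expected[expected$category == cat, ]
    g <- got[got$category == cat, ]
    z <- c(z, abs(g$victims - e$victims) / (g$victims_sd / sqrt(n)),
           abs(g$tangible - e$tangible) / (g$tangible_sd / sqrt(n)))
  }
  # six simultaneous comparisons: all within 4 SE, at most one beyond 3 SE
  expect_lt(max(z), 4)
  expect_lte(sum(z > 3), 1)
})

test_that("summary statistics and histograms describe the trials exactly", {
  fake <- structure(
    list(
      trials = tibble::tibble(
        trial = c(1L, 2L), category = "cat_a",
        leads = c(0, 10), victims = c(0, 10), tangible = c(0, 10),
        intangible = c(0, 10), investigation_cost = c(0, 10)
      ),
      n_trials = 2L, seed = NULL, variant = "annual_uploads"
    ),
    class = "figg_simulation"
  )
  summ <- summarize_simulation(fake, bins = 5)
  row <- summ$stats[summ$stats$category == "cat_a" & summ$stats$outcome == "victims", ]
  expect_equal(row$mean, 5)
  expect_equal(row$min, 0)
  expect_equal(row$max, 10)
  expect_equal(row$median, 5)

  # constant outcomes: zero sd, all quantiles equal
  const <- fake
  const$trials[c("leads", "victims", "tangible", "intangible", "investigation_cost")] <- 4
  csumm <- summarize_simulation(const)
  crow <- csumm$stats[csumm$stats$category == "cat_a" & csumm$stats$outcome == "victims", ]
  expect_equal(crow$sd, 0)
  expect_equal(crow$q2.5, crow$q97.5)

  sim <- run_trials(cfg, n_trials = 400, seed = 2)
  summ2 <- summarize_simulation(sim, bins = 30)
  counts <- summ2$histograms$counts[[1]]
  expect_equal(sum(counts), 400)
  expect_length(summ2$histograms$breaks[[1]], 31)
  expect_error(summarize_simulation(sim, bins = 0), "bins")
})

test_that("the case-total model variant follows its own published table wiring", {
  sim <- run_trials(cfg, n_trials = 2000, seed = 4, variant = "total_cases")
  expected <- oracle_expectation(cfg, variant = "total_cases")
  got <- mean(sim$trials$victims[sim$trials$category == "sexual_assault"])
  e <- expected$victims[expected$category == "sexual_assault"]
  expect_rel(got, e, 0.1)
  # the two wirings genuinely differ
  expect_gt(e, oracle_expectation(cfg)$victims[expected$category == "sexual_assault"])
  expect_error(run_trials(cfg, 10, variant = "nope"))
})

test_that("tidy and glance follow broom conventions", {
  sim <- run_trials(cfg, n_trials = 100, seed = 8)
  td <- tidy(sim)
  expect_true(all(c("category", "outcome", "mean", "sd", "q2.5", "q97.5") %in% names(td)))
  expect_true("combined" %in% td$category)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_trials, 100)
  expect_equal(gl$seed, 8)
})
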