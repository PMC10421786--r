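cfg <- default_config()

test_that("rate arithmetic reproduces the published database statistics", {
  expect_equal(round(100 * ratio_stat(33398, 80325), 1), 41.6)
  expect_equal(round(100 * ratio_stat(15784, 33398), 1), 47.3)
  expect_equal(round(100 * ratio_stat(10550, 15784), 1), 66.8)
  expect_equal(round(100 * overall_success_rate(0.416, 0.473), 1), 19.7)
  expect_equal(overall_success_rate(1, 0.36), 0.36)
  expect_equal(overall_success_rate(0.45, 0.80), 0.36)
  expect_error(overall_success_rate(1.2, 0.5), "\\[0, 1\\]")
  expect_error(ratio_stat(1, 0), "positive")
})

test_that("no-hit pool is total profiles minus lifetime hits", {
  expect_equal(no_hit_pool(cfg$database), 556482)
  expect_equal(no_hit_pool(list(total_forensic_profiles = 10, lifetime_hits = 0)), 10)
  expect_equal(no_hit_pool(list(total_forensic_profiles = 10, lifetime_hits = 10)), 0)
})

test_that("lead chain reproduces the published endpoint counts", {
  expect_equal(round(investigative_leads(556482, 0.05, 0.135, 0.59)), 46540)
  expect_equal(round(investigative_leads(556482, 0.20, 0.20, 0.88)), 117529)
  expect_equal(round(investigative_leads(556482, 0.20, 0.865, 0.88)), 508313)
  expect_equal(round(investigative_leads(114426, 0.20, 0.20, 0.88)), 24167)
  expect_equal(round(investigative_leads(114426, 0.05, 0.135, 0.59)), 9570)
  expect_equal(investigative_leads(1000, 0, 1, 1), 1000)
  expect_error(investigative_leads(-1, 0, 0.5, 0.5), "non-negative")
  expect_error(investigative_leads(10, 0.1, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("victims and savings follow the published chain", {
  expect_equal(round(victims_prevented(investigative_leads(556482, 0.05, 0.135, 0.59), 0.30)), 13962)
  expect_equal(round(victims_prevented(investigative_leads(556482, 0.20, 0.20, 0.88), 0.67)), 78744)
  expect_equal(victims_prevented(100, 0), 0)

  s <- cost_savings(victims_prevented(investigative_leads(556482, 0.05, 0.135, 0.59), 0.30),
                    7419, 133021)
  expect_rel(s$tangible, 103583611, 0.001)
  expect_rel(s$intangible, 1857230822, 0.001)
  expect_equal(cost_savings(0, 7419, 133021), tibble::tibble(tangible = 0, intangible = 0))
  expect_equal(cost_savings(1, 7419, 133021), tibble::tibble(tangible = 7419, intangible = 133021))

  expect_equal(investigation_cost(1000, 50, 46), 2300000)
  expect_equal(investigation_cost(1, 10, 24), 240)
  expect_equal(investigation_cost(0, 50, 46), 0)
})

test_that("lifetime bounding model reproduces published per-pool figures", {
  low <- category_lifetime(cfg, "sexual_assault", "low")
  expect_rel(low$tangible[low$pool == "combined"], 212991099, 0.001)
  expect_rel(low$intangible[low$pool == "combined"], 3818882463, 0.001)
  expect_equal(round(low$victims[low$pool == "hit"]), 14747)

  high <- category_lifetime(cfg, "sexual_assault", "high")
  expect_lte(abs(round(high$victims[high$pool == "hit"]) - 83173), 1)
  expect_rel(high$tangible[high$pool == "combined"], 1201258822, 0.001)
  expect_rel(high$intangible[high$pool == "combined"], 21538300280, 0.001)

  oth_low <- category_lifetime(cfg, "other_crimes", "low")
  expect_equal(round(oth_low$leads[oth_low$pool == "no_hit"]), 275792)
  expect_rel(oth_low$tangible[oth_low$pool == "no_hit"], 683496501, 0.001)
  expect_rel(oth_low$intangible[oth_low$pool == "no_hit"], 2560071267, 0.001)
  oth_high <- category_lifetime(cfg, "other_crimes", "high")
  expect_equal(round(oth_high$leads[oth_high$pool == "no_hit"]), 508313)
  expect_rel(oth_high$tangible[oth_high$pool == "no_hit"], 2729462461, 0.001)
  expect_rel(oth_high$intangible[oth_high$pool == "no_hit"], 10223341902, 0.001)
})

test_that("combined pool is the component-wise sum of hit and no-hit pools", {
  for (setting in c("low", "base", "high")) {
    res <- category_lifetime(cfg, "sexual_assault", setting)
    cols <- c("leads", "victims", "tangible", "intangible", "investigation_cost")
    expect_equal(
      unlist(res[res$pool == "combined", cols]),
      unlist(res[res$pool == "no_hit", cols]) + unlist(res[res$pool == "hit", cols])
    )
    expect_true(all(res$victims <= res$leads))
    expect_true(all(unlist(res[cols]) >= 0))
  }
})

test_that("annual model reproduces published yearly figures", {
  low <- category_annual(cfg, "sexual_assault", "low")
  expect_equal(round(low$leads), 9570)
  expect_rel(low$tangible, 21299354, 0.001)
  expect_rel(low$intangible, 381892614, 0.001)
  high <- category_annual(cfg, "sexual_assault", "high")
  expect_rel(high$tangible, 120126495, 0.001)
  expect_rel(high$intangible, 2153841008, 0.001)

  # the published low victim count (17,103) is a transposition of 17,013:
  # both published dollar figures imply 17,012.9 victims, as does the chain
  oth <- category_annual(cfg, "other_crimes", "low")
  expect_equal(round(oth$victims), 17013)
  expect_rel(oth$tangible, 140543217, 0.001)
  expect_rel(oth$intangible, 526411842, 0.001)
  oth_hi <- category_annual(cfg, "other_crimes", "high")
  expect_equal(round(oth_hi$victims), 67939)
  expect_rel(oth_hi$tangible, 561242720, 0.001)
})

test_that("murder pipeline carries unrounded unsolved cases through the horizon", {
  low <- murder_savings(cfg, "low")
  hz <- low[low$scope == "horizon", ]
  expect_equal(round(hz$unsolved_per_year), 6672)
  expect_equal(round(hz$profiles), 20015)
  expect_equal(round(hz$leads), 12399)
  expect_equal(round(hz$victims), 620)
  expect_rel(hz$tangible, 1648053202, 0.001)
  expect_rel(hz$intangible, 3193315687, 0.001)

  high <- murder_savings(cfg, "high")
  hz2 <- high[high$scope == "horizon", ]
  expect_equal(round(hz2$profiles), 33358)
  expect_equal(round(hz2$leads), 35226)
  expect_equal(round(hz2$victims), 5284)
  expect_rel(hz2$tangible, 14046361433, 0.001)
  expect_rel(hz2$intangible, 27216637334, 0.001)

  # annual x horizon == horizon totals exactly
  an <- low[low$scope == "annual", ]
  for (col in c("leads", "victims", "tangible", "intangible", "investigation_cost")) {
    expect_equal(an[[col]] * cfg$murder$horizon_years, hz[[col]])
  }

  # zero profile yield zeroes everything downstream
  cfg0 <- cfg
  idx <- cfg0$categories$category == "murder" & cfg0$categories$parameter == "upload_ratio"
  cfg0$categories[idx, c("kind", "low", "mode", "high")] <-
    list("point", 0, 0, 0)
  z <- murder_savings(cfg0, "low")
  expect_true(all(z[, c("profiles", "leads", "victims", "tangible", "intangible")] == 0))
})

test_that("composed operations agree with a term-by-term recomputation", {
  for (setting in c("low", "high")) {
    for (cat in c("sexual_assault", "other_crimes")) {
      pick <- function(p, s = setting) {
        row <- cfg$categories[cfg$categories$category == cat &
                                cfg$categories$parameter == p, ]
        dist_endpoint(row$kind, row$low, row$mode, row$high, s)
      }
      res <- category_lifetime(cfg, cat, setting)
      for (pool_name in c("no_hit", "hit")) {
        pool <- if (pool_name == "no_hit") 556482 else 587773
        oracle <- brute_chain(pool, pick("upload_increase"), pick("category_share"),
                              pick("lead_rate"), pick("reduction_rate"),
                              pick("tangible_cost", "base"), pick("intangible_cost", "base"),
                              pick("extra_hours"), pick("police_hourly_rate"))
        got <- res[res$pool == pool_name, ]
        for (col in names(oracle)) {
          expect_rel(got[[col]], oracle[[col]], 1e-9)
        }
      }
    }
  }
})

test_that("outputs are monotone in every chain input", {
  base <- category_annual(cfg, "sexual_assault", "high")
  params <- c("upload_increase", "category_share", "lead_rate", "reduction_rate",
              "extra_hours", "police_hourly_rate")
  for (p in params) {
    cfg2 <- cfg
    idx <- cfg2$categories$category == "sexual_assault" & cfg2$categories$parameter == p
    shrunk <- cfg2$categories$high[idx] * 0.9
    cfg2$categories$high[idx] <- shrunk
    cfg2$categories$mode[idx] <- pmin(cfg2$categories$mode[idx], shrunk)
    less <- category_annual(cfg2, "sexual_assault", "high")
    expect_lte(less$victims, base$victims)
    expect_lte(less$tangible, base$tangible)
    expect_lte(less$investigation_cost, base$investigation_cost)
  }
  # cost inputs enter at base case: lowering the mode lowers savings
  cfg3 <- cfg
  idx <- cfg3$categories$category == "sexual_assault" & cfg3$categories$parameter == "tangible_cost"
  cfg3$categories$mode[idx] <- 6000
  expect_lt(category_annual(cfg3, "sexual_assault", "high")$tangible, base$tangible)
})

test_that("intermediate settings stay inside the endpoint envelope", {
  lo <- category_annual(cfg, "sexual_assault", "low")
  mid <- category_annual(cfg, "sexual_assault", "base")
  hi <- category_annual(cfg, "sexual_assault", "high")
  for (col in c("leads", "victims", "tangible", "intangible")) {
    expect_gte(mid[[col]], lo[[col]])
    expect_lte(mid[[col]], hi[[col]])
  }
})

test_that("grand totals sum combined rows per scope and reproduce annual totals", {
  res <- static_analysis(cfg)
  tot <- grand_totals(res)
  an_lo <- tot[tot$scope == "annual" & tot$setting == "low", ]
  expect_rel(an_lo$tangible, 326647891, 0.001)
  expect_rel(an_lo$intangible, 1227636025, 0.001)
  expect_rel(an_lo$total, 1554283916, 0.001)
  an_hi <- tot[tot$scope == "annual" & tot$setting == "high", ]
  expect_rel(an_hi$tangible, 2086005358, 0.001)
  expect_rel(an_hi$intangible, 6977668191, 0.001)
  expect_rel(an_hi$total, 9063673549, 0.001)

  empty <- grand_totals(res[0, ])
  expect_equal(nrow(empty), 0)
})
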