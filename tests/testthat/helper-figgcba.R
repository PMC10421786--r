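# Shared fixtures and small oracles for the test suite.

# Collapse every uncertain input of a config to a point mass at its base
# case; Monte Carlo runs on such a config must reduce to the static model.
point_config <- function(cfg, at = "mode") {
  cats <- cfg$categories
  value <- cats[[at]]
  cats$kind <- "point"
  cats$low <- value
  cats$mode <- value
  cats$high <- value
  cfg$categories <- cats
  cfg
}

# Term-by-term recomputation of the lead/victim/savings chain with no
# algebraic simplification; independent oracle for the composed functions.
brute_chain <- function(pool, u, p, h, r, ct, ci, hours, rate) {
  grown <- pool + pool * u
  in_category <- grown * p
  leads <- in_category * h
  victims <- leads * r
  list(
    leads = leads,
    victims = victims,
    tangible = victims * ct,
    intangible = victims * ci,
    investigation_cost = (leads * hours) * rate
  )
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# Endpoint lookups on a config's category table.
param_at <- function(cfg, category, parameter, setting) {
  row <- cfg$categories[cfg$categories$category == category &
                          cfg$categories$parameter == parameter, ]
  dist_endpoint(row$kind, row$low, row$mode, row$high, setting)
}
param_low <- function(cfg, category, parameter) param_at(cfg, category, parameter, "low")
param_high <- function(cfg, category, parameter) param_at(cfg, category, parameter, "high")

lookup_reagent <- function(cfg, name) {
  tbl <- per_sample_cost(cfg$costs$reagents)
  tbl$per_sample[tbl$name == name]
}

# Triangular distribution closed forms used as sampling oracles.
tri_cdf <- function(x, lo, mo, hi) {
  ifelse(x <= lo, 0,
  ifelse(x >= hi, 1,
  ifelse(x < mo, (x - lo)^2 / ((hi - lo) * (mo - lo)),
         1 - (hi - x)^2 / ((hi - lo) * (hi - mo)))))
}
tri_var <- function(lo, mo, hi) {
  (lo^2 + mo^2 + hi^2 - lo * mo - lo * hi - mo * hi) / 18
}
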