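#' Generate a synthetic, internally consistent scenario
#'
#' Produces a random configuration with the same statistical structure the
#' analysis assumes — independent triangular/uniform inputs feeding a
#' multiplicative lead/victim/savings chain — so every stage of the
#' pipeline can be exercised without external data. Generated database
#' counts respect all ordering invariants; generated distributions pass
#' [validate_config()] and survive a save/load round trip.
#'
#' Triangular modes are drawn uniformly inside \[low, high\]; with 10%
#' probability the mode is placed exactly on the upper bound to exercise
#' the right-degenerate triangles that occur in the packaged fixture
#' (victim-reduction rates whose base case equals the maximum).
#'
#' @param seed Integer seed; the scenario is a deterministic function of it.
#' @param n_categories Number of synthetic crime categories (0 gives a
#'   config with database/murder blocks only).
#' @param include_murder Also generate the murder block's category
#'   parameters (default `TRUE`).
#' @param tangible_range,intangible_range Cost bound family (USD): each
#'   category's cost bounds are drawn inside these.
#' @param cases_range Annual case-total family.
#' @param pool_range Range for total forensic profiles in the database.
#' @return A `figg_config`.
#' @examples
#' generate_scenario(seed = 1, n_categories = 2)
#' @export
generate_scenario <- function(seed, n_categories = 2, include_murder = TRUE,
                              tangible_range = c(5000, 10000),
                              intangible_range = c(100000, 165000),
                              cases_range = c(330000, 400000),
                              pool_range = c(5e5, 2e6)) {
  if (any(diff(tangible_range) < 0, diff(intangible_range) < 0,
          diff(cases_range) < 0, diff(pool_range) < 0)) {
    abort("infeasible bounds: each range must be increasing")
  }
  set.seed(seed)
  r_in <- function(rng) runif(1, rng[1], rng[2])

  total <- round(r_in(pool_range))
  hits <- round(total * runif(1, 0.3, 0.7))
  completed <- round(runif(1, 2e4, 1e5))
  uploaded <- round(completed * runif(1, 0.3, 0.7))
  saki_hits <- round(uploaded * runif(1, 0.3, 0.7))
  serial <- round(saki_hits * runif(1, 0.3, 0.9))
  funding <- sort(round(runif(2, 5e8, 5e9)))
  database <- list(
    total_forensic_profiles = total, lifetime_hits = hits,
    annual_uploads = round(total / 10),
    saki_completed_kits = completed, saki_uploaded = uploaded,
    saki_hits = saki_hits, saki_serial_hits = serial,
    funding_low = funding[1], funding_high = funding[2]
  )
  murder <- list(
    reported_per_year = round(runif(1, 5e3, 2e4)),
    clearance_rate = runif(1, 0.3, 0.9),
    horizon_years = sample(5:15, 1)
  )

  tri_in <- function(rng, proportion = FALSE) {
    b <- sort(runif(2, rng[1], rng[2]))
    mode <- if (runif(1) < 0.1) b[2] else runif(1, b[1], b[2])
    tibble(kind = "triangular", low = b[1], mode = mode, high = b[2],
           proportion = proportion)
  }
  unif_in <- function(rng, proportion = FALSE) {
    b <- sort(runif(2, rng[1], rng[2]))
    tibble(kind = "uniform", low = b[1], mode = mean(b), high = b[2],
           proportion = proportion)
  }
  category_block <- function(name, with_share = TRUE) {
    specs <- list(
      tangible_cost = tri_in(tangible_range),
      intangible_cost = tri_in(intangible_range),
      upload_increase = tri_in(c(0.02, 0.25), proportion = TRUE),
      upload_ratio = tri_in(c(0.3, 0.6), proportion = TRUE),
      total_cases = tri_in(cases_range),
      lead_rate = tri_in(c(0.5, 0.95), proportion = TRUE),
      reduction_rate = tri_in(c(0.05, 0.7), proportion = TRUE),
      extra_hours = tri_in(c(5, 60)),
      police_hourly_rate = tri_in(c(20, 80))
    )
    if (with_share) specs$category_share <- unif_in(c(0.05, 0.95), proportion = TRUE)
    bind_rows(specs, .id = "parameter") |>
      mutate(category = name, .before = 1)
  }

  blocks <- list()
  if (n_categories > 0) {
    for (i in seq_len(n_categories)) {
      blocks[[i]] <- category_block(paste0("category_", i))
    }
  }
  if (include_murder) {
    blocks[[length(blocks) + 1L]] <- category_block("murder", with_share = FALSE)
  }
  categories <- if (length(blocks)) bind_rows(blocks) else empty_categories()

  cfg <- structure(
    list(database = database, murder = murder, categories = categories,
         costs = default_costs_block()),
    class = "figg_config"
  )
  problems <- validate_config(cfg)
  if (length(problems)) {
    abort(paste0("generated scenario failed validation: ",
                 paste(problems, collapse = "; ")))
  }
  cfg
}

empty_categories <- function() {
  tibble(category = character(), parameter = character(), kind = character(),
         low = numeric(), mode = numeric(), high = numeric(),
         proportion = logical())
}

default_costs_block <- function() {
  list(
    reagents = reagent_spec("generic", 10000, 10, run_kit_cost = 1000, plexity = 5),
    budget = tibble(scenario = character(), name = character(),
                    total_cost = numeric(), amortization_years = numeric()),
    caseload = list(requests_low = 0, requests_high = 0, samples_per_request = 0),
    database_population = list(samples_per_year = 0),
    microarray_per_sample = 0,
    missing_persons = NULL
  )
}

#' Closed-form expected outcomes of the Monte Carlo chain
#'
#' Because every trial outcome is a product of independently sampled
#' factors times a fixed scale, its expectation is the product of the
#' factors' analytic means (triangular mean `(low + mode + high)/3`,
#' uniform mean the midpoint). This is an independent oracle for
#' [run_trials()]: simulated means must converge to these values.
#'
#' @param config A `figg_config`.
#' @param variant Model variant, as in [run_trials()].
#' @return A tibble with one row per category (plus `combined`) and the
#'   expected value of each outcome.
#' @examples
#' oracle_expectation(default_config())
#' @export
oracle_expectation <- function(config, variant = c("annual_uploads", "total_cases")) {
  variant <- arg_match(variant)
  cats <- unique(config$categories$category)
  rows <- lapply(cats, function(cat) {
    spec <- chain_spec(config, cat, variant)
    means <- setNames(
      as.list(dist_mean(spec$inputs$kind, spec$inputs$low,
                        spec$inputs$mode, spec$inputs$high)),
      spec$inputs$parameter
    )
    mutate(eval_chain(spec, means), category = cat, .before = 1)
  })
  per_cat <- bind_rows(rows)
  combined <- per_cat |>
    summarise(across(all_of(sim_outcomes), sum)) |>
    mutate(category = "combined", .before = 1)
  bind_rows(per_cat, combined)
}

#' Exact outcome distribution by enumeration
#'
#' For a multiplicative chain whose inputs all have small discrete
#' supports, enumerates every combination and returns the exact outcome
#' distribution. Used as an oracle for the sampling engine: the empirical
#' distribution of [sample_chain()] on the same inputs must converge to it
#' in total variation.
#'
#' @param inputs Named list; each element a list with `values` and `probs`
#'   (probabilities need not be normalised). At most 6 inputs of at most 5
#'   support points each.
#' @param scale Fixed multiplier applied to every outcome.
#' @return A tibble with columns `outcome` and `prob` (summing to 1),
#'   aggregated over combinations yielding the same product.
#' @examples
#' oracle_enumeration(list(a = list(values = c(1, 2), probs = c(.5, .5))))
#' @export
oracle_enumeration <- function(inputs, scale = 1) {
  if (length(inputs) > 6) abort("support too large: at most 6 inputs")
  sizes <- vapply(inputs, function(x) length(x$values), integer(1))
  if (any(sizes > 5)) abort("support too large: at most 5 points per input")
  if (any(sizes < 1)) abort("each input needs at least one support point")
  grids <- expand.grid(lapply(inputs, function(x) seq_along(x$values)))
  outcome <- rep(scale, nrow(grids))
  prob <- rep(1, nrow(grids))
  for (j in seq_along(inputs)) {
    idx <- grids[[j]]
    p <- inputs[[j]]$probs / sum(inputs[[j]]$probs)
    outcome <- outcome * inputs[[j]]$values[idx]
    prob <- prob * p[idx]
  }
  tibble(outcome = outcome, prob = prob) |>
    group_by(.data$outcome) |>
    summarise(prob = sum(.data$prob), .groups = "drop") |>
    arrange(.data$outcome)
}

#' Sample the multiplicative chain directly
#'
#' Draws each input independently (via the same sampling engine the Monte
#' Carlo trials use, see [dist_sample()]) and returns the product chain's
#' outcomes. Discrete inputs may be given as `values`/`probs` lists as in
#' [oracle_enumeration()].
#'
#' @param inputs Named list of distribution descriptions: either
#'   `list(values =, probs =)` (discrete) or `list(kind =, low =, mode =,
#'   high =)`.
#' @param n Number of draws.
#' @param scale Fixed multiplier.
#' @param seed Optional seed.
#' @return Numeric vector of `n` outcomes.
#' @export
sample_chain <- function(inputs, n, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- rep(scale, n)
  for (x in inputs) {
    draw <- if (!is.null(x$values)) {
      dist_sample(n, "discrete", values = x$values, probs = x$probs,
                  low = min(x$values), mode = x$values[1], high = max(x$values))
    } else {
      dist_sample(n, x$kind, x$low, x$mode %||% (x$low + x$high) / 2, x$high)
    }
    out <- out * draw
  }
  out
}
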