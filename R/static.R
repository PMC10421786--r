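#' Overall database success rate
#'
#' The probability that a completed evidence kit both yields an uploadable
#' profile and produces a hit or investigative lead: the product of the
#' upload rate and the hit rate.
#'
#' @param upload_rate Fraction of completed kits yielding an uploadable
#'   profile, in \[0, 1\].
#' @param hit_rate Fraction of uploaded profiles producing a hit or lead,
#'   in \[0, 1\].
#' @return The overall success rate, in \[0, 1\]. Vectorised.
#' @examples
#' overall_success_rate(0.416, 0.473) # ~0.197
#' @export
overall_success_rate <- function(upload_rate, hit_rate) {
  check_fraction(upload_rate, "upload_rate")
  check_fraction(hit_rate, "hit_rate")
  upload_rate * hit_rate
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(paste0(name, " must lie in [0, 1]"))
  }
  invisible(x)
}

#' Simple rate from two counts
#'
#' Used for the database statistics the model is seeded with, e.g. the
#' upload rate (profiles uploaded / kits completed) and hit rate
#' (hits / profiles uploaded).
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @return `numerator / denominator`. Vectorised.
#' @examples
#' ratio_stat(33398, 80325) # upload rate ~0.416
#' ratio_stat(15784, 33398) # hit rate ~0.473
#' @export
ratio_stat <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  numerator / denominator
}

#' Forensic profiles that have never hit
#'
#' The pool of database profiles available for new kinship-based leads:
#' total forensic profiles minus lifetime hits (assuming one hit per
#' profile).
#'
#' @param database Named list of database counts (see [default_config()]).
#' @return A count.
#' @examples
#' no_hit_pool(default_config()$database) # 556482
#' @export
no_hit_pool <- function(database) {
  database$total_forensic_profiles - database$lifetime_hits
}

#' Investigative leads from a profile pool
#'
#' The core multiplicative chain: a pool of profiles, grown by the upload
#' increase `(1 + u)` the more sensitive assay affords, thinned to the
#' crime category's share `p` of profiles, and converted to leads at the
#' kinship lead rate `h`.
#'
#' @param pool Profile pool size (count, may be fractional).
#' @param upload_increase Fractional increase in uploadable profiles, `>= 0`.
#' @param category_share Category's share of the pool, in \[0, 1\].
#' @param lead_rate Investigative lead rate, in \[0, 1\].
#' @return Expected number of leads (unrounded; round only for display).
#' @examples
#' investigative_leads(556482, 0.05, 0.135, 0.59) # ~46540
#' @export
investigative_leads <- function(pool, upload_increase, category_share, lead_rate) {
  if (any(pool < 0)) abort("pool must be non-negative")
  if (any(upload_increase < 0)) abort("upload_increase must be non-negative")
  check_fraction(category_share, "category_share")
  check_fraction(lead_rate, "lead_rate")
  pool * (1 + upload_increase) * category_share * lead_rate
}

#' Victims prevented from investigative leads
#'
#' Leads acting on serial recidivists prevent future victims at the
#' recidivism/victim-reduction rate.
#'
#' @param leads Number of investigative leads.
#' @param reduction_rate Recidivism/victim-reduction rate, in \[0, 1\].
#' @return Expected number of prevented victims.
#' @examples
#' victims_prevented(46540, 0.30)
#' @export
victims_prevented <- function(leads, reduction_rate) {
  check_fraction(reduction_rate, "reduction_rate")
  leads * reduction_rate
}

#' Monetised savings from prevented victims
#'
#' @param victims Number of prevented victims.
#' @param tangible_cost,intangible_cost Per-case costs in USD.
#' @return A tibble with columns `tangible` and `intangible` (USD).
#' @examples
#' cost_savings(13962, 7419, 133021)
#' @export
cost_savings <- function(victims, tangible_cost, intangible_cost) {
  if (any(c(victims, tangible_cost, intangible_cost) < 0)) {
    abort("victims and costs must be non-negative")
  }
  tibble(tangible = victims * tangible_cost, intangible = victims * intangible_cost)
}

#' Additional police investigation cost
#'
#' Genealogy follow-up lengthens investigations; the cost is the number of
#' leads times extra hours per investigation times the police hourly rate.
#' Reported as its own line, never netted from savings by default.
#'
#' @param leads Number of investigative leads.
#' @param extra_hours Extra hours per investigation.
#' @param hourly_rate Police hourly rate in USD.
#' @return USD.
#' @examples
#' investigation_cost(1000, 50, 46)
#' @export
investigation_cost <- function(leads, extra_hours, hourly_rate) {
  if (any(c(leads, extra_hours, hourly_rate) < 0)) abort("inputs must be non-negative")
  leads * extra_hours * hourly_rate
}

# Evaluate the full lead -> victims -> savings chain for one pool.
# Costs are evaluated at the base case (mode) in the bounding model: the
# published static chains pair endpoint rates with base-case per-case costs.
chain_result <- function(pool, u, p, h, r, ct, ci, hours, rate) {
  leads <- pool * (1 + u) * p * h
  victims <- leads * r
  tibble(
    leads = leads,
    victims = victims,
    tangible = victims * ct,
    intangible = victims * ci,
    investigation_cost = leads * hours * rate
  )
}

category_rate_endpoints <- function(config, category, setting) {
  list(
    u = param_endpoint(config, category, "upload_increase", setting),
    p = param_endpoint(config, category, "category_share", setting),
    h = param_endpoint(config, category, "lead_rate", setting),
    r = param_endpoint(config, category, "reduction_rate", setting),
    ct = param_endpoint(config, category, "tangible_cost", "base"),
    ci = param_endpoint(config, category, "intangible_cost", "base"),
    hours = param_endpoint(config, category, "extra_hours", setting),
    rate = param_endpoint(config, category, "police_hourly_rate", setting)
  )
}

#' Lifetime bounding model for one crime category
#'
#' Applies the lead/victim/savings chain to both database pools — profiles
#' that have never hit (`no_hit`) and lifetime hits (`hit`) — with all
#' uncertain rates set simultaneously to the chosen endpoint, and sums them
#' (`combined`). Per-case tangible/intangible costs stay at their base
#' case; see the methods vignette.
#'
#' @param config A `figg_config`.
#' @param category `"sexual_assault"` or `"other_crimes"` (murder has its
#'   own front end, see [murder_savings()]).
#' @param setting `"low"`, `"base"` or `"high"`: every rate goes to that
#'   endpoint at once.
#' @return A tibble with one row per pool (`no_hit`, `hit`, `combined`) and
#'   columns `category`, `scope`, `setting`, `pool`, `leads`, `victims`,
#'   `tangible`, `intangible`, `investigation_cost`.
#' @examples
#' category_lifetime(default_config(), "sexual_assault", "low")
#' @export
category_lifetime <- function(config, category, setting = c("low", "base", "high")) {
  setting <- arg_match(setting)
  e <- category_rate_endpoints(config, category, setting)
  pools <- c(no_hit = no_hit_pool(config$database), hit = config$database$lifetime_hits)
  res <- bind_rows(lapply(pools, function(pool) {
    chain_result(pool, e$u, e$p, e$h, e$r, e$ct, e$ci, e$hours, e$rate)
  }))
  res <- bind_rows(res, summarise(res, across(everything(), sum)))
  mutate(res,
    category = category, scope = "lifetime", setting = setting,
    pool = c("no_hit", "hit", "combined"), .before = 1
  )
}

#' Annual bounding model for one crime category
#'
#' The annual chain applies the same rates to the yearly upload stream
#' (all profiles uploaded per year, with no hit/no-hit split).
#'
#' @inheritParams category_lifetime
#' @return A one-row tibble (`pool = "combined"`).
#' @examples
#' category_annual(default_config(), "sexual_assault", "low")
#' @export
category_annual <- function(config, category, setting = c("low", "base", "high")) {
  setting <- arg_match(setting)
  e <- category_rate_endpoints(config, category, setting)
  res <- chain_result(config$database$annual_uploads, e$u, e$p, e$h, e$r,
                      e$ct, e$ci, e$hours, e$rate)
  mutate(res,
    category = category, scope = "annual", setting = setting,
    pool = "combined", .before = 1
  )
}

#' Murder bounding model (horizon and annual)
#'
#' Murder enters through its own front end: unsolved cases per year are
#' reported murders times the uncleared fraction; a fraction of those
#' (the profile yield, the murder `upload_ratio` parameter) yields
#' uploadable profiles, accumulated over the projection horizon. Leads are
#' then `profiles x (1 + u) x h`, and prevented victims come from the
#' serial-murder reduction rate. Intermediates are carried unrounded;
#' annual results are horizon totals divided by the horizon.
#'
#' @param config A `figg_config`.
#' @param setting `"low"`, `"base"` or `"high"`.
#' @return A two-row tibble (scopes `horizon` and `annual`), same columns
#'   as [category_lifetime()], plus attribute-free helper columns
#'   `unsolved_per_year` and `profiles`.
#' @examples
#' murder_savings(default_config(), "low")
#' @export
murder_savings <- function(config, setting = c("low", "base", "high")) {
  setting <- arg_match(setting)
  mu <- config$murder
  unsolved <- mu$reported_per_year * (1 - mu$clearance_rate)
  yield <- param_endpoint(config, "murder", "upload_ratio", setting)
  u <- param_endpoint(config, "murder", "upload_increase", setting)
  h <- param_endpoint(config, "murder", "lead_rate", setting)
  r <- param_endpoint(config, "murder", "reduction_rate", setting)
  ct <- param_endpoint(config, "murder", "tangible_cost", "base")
  ci <- param_endpoint(config, "murder", "intangible_cost", "base")
  hours <- param_endpoint(config, "murder", "extra_hours", setting)
  rate <- param_endpoint(config, "murder", "police_hourly_rate", setting)

  profiles <- unsolved * yield * mu$horizon_years
  leads <- profiles * (1 + u) * h
  victims <- leads * r
  horizon <- tibble(
    category = "murder", scope = "horizon", setting = setting, pool = "combined",
    unsolved_per_year = unsolved, profiles = profiles,
    leads = leads, victims = victims,
    tangible = victims * ct, intangible = victims * ci,
    investigation_cost = leads * hours * rate
  )
  annual <- mutate(horizon,
    scope = "annual",
    across(all_of(c("profiles", "leads", "victims", "tangible",
                    "intangible", "investigation_cost")),
           ~ .x / mu$horizon_years)
  )
  bind_rows(horizon, annual)
}

#' Full static bounding analysis
#'
#' Runs [category_lifetime()], [category_annual()] and [murder_savings()]
#' for the requested settings and stacks the results. Murder's horizon
#' totals are reported under scope `"lifetime"` alongside the other
#' categories' database-lifetime totals, as in the published summary table.
#'
#' @param config A `figg_config`.
#' @param settings Character vector of settings to evaluate.
#' @return A tibble of savings results (one row per category x scope x
#'   setting x pool).
#' @examples
#' static_analysis(default_config())
#' @export
static_analysis <- function(config, settings = c("low", "high")) {
  main <- setdiff(unique(config$categories$category), "murder")
  rows <- list()
  for (s in settings) {
    for (cat in main) {
      rows[[length(rows) + 1L]] <- category_lifetime(config, cat, s)
      rows[[length(rows) + 1L]] <- category_annual(config, cat, s)
    }
    mr <- select(murder_savings(config, s), -all_of(c("unsolved_per_year", "profiles")))
    mr$scope[mr$scope == "horizon"] <- "lifetime"
    rows[[length(rows) + 1L]] <- mr
  }
  bind_rows(rows)
}

#' Totals across crime categories
#'
#' Sums tangible and intangible savings (and their total) over categories,
#' per scope and setting, using each category's combined pool.
#'
#' @param results A savings tibble from [static_analysis()] (or compatible).
#' @return A tibble with columns `scope`, `setting`, `tangible`,
#'   `intangible`, `total`.
#' @examples
#' grand_totals(static_analysis(default_config()))
#' @export
grand_totals <- function(results) {
  if (nrow(results) == 0) {
    return(tibble(scope = character(), setting = character(),
                  tangible = numeric(), intangible = numeric(), total = numeric()))
  }
  results |>
    filter(.data$pool == "combined") |>
    group_by(.data$scope, .data$setting) |>
    summarise(
      tangible = sum(.data$tangible),
      intangible = sum(.data$intangible),
      .groups = "drop"
    ) |>
    mutate(total = .data$tangible + .data$intangible)
}

#' Static outcome envelope for Monte Carlo containment
#'
#' Evaluates the per-category annual (or total-cases) chain with *every*
#' uncertain input — including per-case costs and labor — pushed to its
#' low or high endpoint. Because the chain is a product of non-negative
#' factors it is monotone in each input, so these are the exact attainable
#' bounds for any sampled trial; used to check simulation output.
#'
#' @param config A `figg_config`.
#' @param variant Model variant, as in [run_trials()].
#' @return A tibble with one row per category x outcome and columns
#'   `min`, `max`.
#' @export
static_envelope <- function(config, variant = c("annual_uploads", "total_cases")) {
  variant <- arg_match(variant)
  cats <- unique(config$categories$category)
  rows <- list()
  for (cat in cats) {
    spec <- chain_spec(config, cat, variant)
    out_lo <- eval_chain(spec, endpoint_values(spec, "low"))
    out_hi <- eval_chain(spec, endpoint_values(spec, "high"))
    rows[[cat]] <- tibble(
      category = cat,
      outcome = names(out_lo),
      min = pmin(unlist(out_lo), unlist(out_hi)),
      max = pmax(unlist(out_lo), unlist(out_hi))
    )
  }
  per_cat <- bind_rows(rows)
  combined <- per_cat |>
    group_by(.data$outcome) |>
    summarise(min = sum(.data$min), max = sum(.data$max), .groups = "drop") |>
    mutate(category = "combined", .before = 1)
  bind_rows(per_cat, combined)
}
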