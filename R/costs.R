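#' Describe a sequencing reagent configuration
#'
#' A reagent configuration is a library-preparation price (either a kit
#' price split over its kit size, or a flat per-library price) plus a
#' sequencing run kit whose cost is divided by the plexity (libraries
#' pooled per run).
#'
#' @param name Label.
#' @param library_kit_cost,library_kit_size Kit price (USD) and libraries
#'   per kit. Supply either this pair or `per_library_override`.
#' @param per_library_override Flat per-library price (USD).
#' @param run_kit_cost Sequencing run kit price (USD); 0 for platforms
#'   with no separate run kit (e.g. microarrays).
#' @param plexity Libraries per sequencing run, `>= 1`.
#' @return A one-row tibble.
#' @examples
#' reagent_spec("kintelligence", 11499, 12, run_kit_cost = 1500, plexity = 3)
#' @export
reagent_spec <- function(name, library_kit_cost = NA_real_, library_kit_size = NA_real_,
                         per_library_override = NA_real_, run_kit_cost = 0, plexity = 1) {
  out <- tibble(
    name = name,
    library_kit_cost = as.numeric(library_kit_cost),
    library_kit_size = as.numeric(library_kit_size),
    per_library_override = as.numeric(per_library_override),
    run_kit_cost = as.numeric(run_kit_cost),
    plexity = as.numeric(plexity)
  )
  has_kit <- !is.na(out$library_kit_cost) & !is.na(out$library_kit_size)
  has_flat <- !is.na(out$per_library_override)
  if (any(has_kit == has_flat)) {
    abort("supply exactly one of (library_kit_cost, library_kit_size) or per_library_override")
  }
  if (any(out$plexity < 1) || any(has_kit & out$library_kit_size < 1)) {
    abort("plexity and library_kit_size must be >= 1")
  }
  out
}

#' Reagent cost per sample
#'
#' Library preparation cost per sample plus the run kit cost split across
#' the run's plexity, reported to the cent.
#'
#' @param reagents A reagent tibble ([reagent_spec()] rows, or the
#'   `costs$reagents` table of a config).
#' @return The input tibble with a `per_sample` column (USD, rounded to
#'   cents).
#' @examples
#' per_sample_cost(reagent_spec("kint12", 11499, 12, run_kit_cost = 1500, plexity = 3))
#' @export
per_sample_cost <- function(reagents) {
  if (any(reagents$plexity < 1)) abort("plexity must be >= 1")
  library_cost <- ifelse(
    is.na(reagents$per_library_override),
    reagents$library_kit_cost / reagents$library_kit_size,
    reagents$per_library_override
  )
  mutate(reagents, per_sample = round(library_cost + .data$run_kit_cost / .data$plexity, 2))
}

lookup_per_sample <- function(config, spec_name) {
  row <- filter(config$costs$reagents, .data$name == spec_name)
  if (nrow(row) != 1) abort(paste0("reagent spec '", spec_name, "' not found"))
  per_sample_cost(row)$per_sample
}

#' National annual casework reagent cost
#'
#' @param requests_per_year Casework requests per year.
#' @param samples_per_request Samples per request.
#' @param per_sample Reagent cost per sample (USD).
#' @return USD per year. Vectorised.
#' @examples
#' caseload_cost(400000, 5, 289.58)
#' @export
caseload_cost <- function(requests_per_year, samples_per_request, per_sample) {
  if (any(c(requests_per_year, samples_per_request, per_sample) < 0)) {
    abort("inputs must be non-negative")
  }
  requests_per_year * samples_per_request * per_sample
}

#' Annual reference-database population cost
#'
#' @param samples_per_year Reference samples typed per year.
#' @param per_sample Reagent cost per sample (USD).
#' @return USD per year. Vectorised.
#' @examples
#' database_population_cost(1e6, 120)
#' @export
database_population_cost <- function(samples_per_year, per_sample) {
  if (any(c(samples_per_year, per_sample) < 0)) abort("inputs must be non-negative")
  samples_per_year * per_sample
}

#' Annualise budget lines
#'
#' Capital lines are straight-line amortised over their stated number of
#' years; annual lines pass through.
#'
#' @param budget A tibble with columns `name`, `total_cost`,
#'   `amortization_years` (and optionally `scenario`).
#' @return The tibble with an `annual_cost` column.
#' @export
budget_lines <- function(budget) {
  if (any(budget$amortization_years < 1)) abort("amortization_years must be >= 1")
  mutate(budget, annual_cost = .data$total_cost / .data$amortization_years)
}

#' Total annual budget
#'
#' @param budget A budget tibble (see [budget_lines()]). An empty tibble
#'   gives zero.
#' @return If a `scenario` column is present, a tibble of per-scenario
#'   annual totals; otherwise a single number (USD per year).
#' @examples
#' annual_budget(default_config()$costs$budget)
#' @export
annual_budget <- function(budget) {
  if (is.null(budget) || nrow(budget) == 0) return(0)
  lines <- budget_lines(budget)
  if ("scenario" %in% names(lines)) {
    lines |>
      group_by(.data$scenario) |>
      summarise(annual_cost = sum(.data$annual_cost), .groups = "drop")
  } else {
    sum(lines$annual_cost)
  }
}

#' Projected cost per investigative lead
#'
#' Annual system budget divided by the projected annual investigative
#' leads, `annual_uploads x (1 + upload_increase) x lead_rate`.
#'
#' @param budget Annual budget (USD/year).
#' @param annual_uploads Profiles uploaded per year.
#' @param upload_increase Fractional upload increase.
#' @param lead_rate Investigative lead rate.
#' @param round Round to whole dollars for display (default `TRUE`).
#' @return USD per lead. Vectorised.
#' @examples
#' cost_per_lead(943090000, 114426, 0.05, 0.59) # 13304
#' @export
cost_per_lead <- function(budget, annual_uploads, upload_increase, lead_rate,
                          round = TRUE) {
  leads <- annual_uploads * (1 + upload_increase) * lead_rate
  if (any(leads <= 0 & budget > 0)) abort("leads must be positive")
  out <- ifelse(budget == 0, 0, budget / leads)
  if (round) round(out) else out
}

#' Historical cost per database hit
#'
#' Cumulative funding divided by lifetime hits.
#'
#' @param funding Cumulative funding (USD).
#' @param hits Lifetime hit count, `> 0`.
#' @param round Round to whole dollars (default `TRUE`).
#' @return USD per hit. Vectorised.
#' @examples
#' historical_cost_per_hit(2e9, 587773) # 3403
#' @export
historical_cost_per_hit <- function(funding, hits, round = TRUE) {
  if (any(hits <= 0)) abort("hits must be positive")
  out <- funding / hits
  if (round) round(out) else out
}

table7_scenarios <- function(config) {
  db <- config$database
  budgets <- annual_budget(config$costs$budget)
  budget_of <- function(s) budgets$annual_cost[budgets$scenario == s]
  # worst case pairs the high budget with low performance, and vice versa
  tibble(
    scenario = c("high_cost_low_yield", "low_cost_high_yield"),
    budget_scenario = c("high", "low"),
    samples_per_year = db$annual_uploads,
    upload_increase = c(param_endpoint(config, "sexual_assault", "upload_increase", "low"),
                        param_endpoint(config, "sexual_assault", "upload_increase", "high")),
    lead_rate = c(param_endpoint(config, "sexual_assault", "lead_rate", "low"),
                  param_endpoint(config, "sexual_assault", "lead_rate", "high")),
    cost_per_year = c(budget_of("high"), budget_of("low"))
  )
}

#' Microarray reference-database alternative
#'
#' Recomputes the annual budget and cost per investigative lead with the
#' database-population line repriced at a microarray per-sample cost
#' (genotyping arrays have no run kit, so the per-sample price is just the
#' kit price over its size).
#'
#' @param config A `figg_config`.
#' @param array_per_sample Microarray cost per sample (USD); defaults to
#'   the config's `microarray_per_sample`.
#' @return A tibble with one row per budget scenario: repriced
#'   `annual_cost` and display-rounded `cost_per_lead` (high budget paired
#'   with low lead yield and vice versa, as in the budget projections).
#' @examples
#' microarray_alternative(default_config())
#' @export
microarray_alternative <- function(config, array_per_sample = NULL) {
  array_per_sample <- array_per_sample %||% config$costs$microarray_per_sample
  budget <- config$costs$budget
  samples <- config$costs$database_population$samples_per_year
  budget$total_cost[budget$name == "database_work"] <-
    database_population_cost(samples, array_per_sample)
  cfg2 <- config
  cfg2$costs$budget <- budget
  scen <- table7_scenarios(cfg2)
  mutate(scen,
    annual_cost = .data$cost_per_year,
    cost_per_lead = cost_per_lead(.data$cost_per_year, .data$samples_per_year,
                                  .data$upload_increase, .data$lead_rate)
  ) |>
    select(all_of(c("budget_scenario", "annual_cost", "upload_increase",
                    "lead_rate", "cost_per_lead")))
}

#' Reagent cost comparison for missing-person casework
#'
#' Missing-person identifications carry no published tangible/intangible
#' crime costs, so the model compares per-sample reagent costs only:
#' current STR/mitochondrial typing versus a large SNP panel, for family
#' reference samples and human remains.
#'
#' @param config A `figg_config`.
#' @return A tibble with one row per sample type: current cost range and
#'   large-SNP-panel per-sample cost.
#' @examples
#' missing_persons_comparison(default_config())
#' @export
missing_persons_comparison <- function(config) {
  mp <- config$costs$missing_persons
  tibble(
    sample_type = c("reference", "remains"),
    current_low = c(mp$current_reference, mp$current_remains_low),
    current_high = c(mp$current_reference, mp$current_remains_high),
    figg = c(lookup_per_sample(config, mp$figg_reference_spec),
             lookup_per_sample(config, mp$figg_remains_spec))
  ) |>
    mutate(difference_vs_current_high = .data$figg - .data$current_high)
}
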