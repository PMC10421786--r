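#' Format US dollars
#'
#' Thousands separators, no decimals for aggregates; cents for per-sample
#' prices.
#'
#' @param x Numeric vector (USD).
#' @param cents Keep cents (default `FALSE`).
#' @return Character vector like `"$1,458.25"`.
#' @export
format_usd <- function(x, cents = FALSE) {
  paste0("$", formatC(round(x, if (cents) 2 else 0),
                      format = "f", digits = if (cents) 2 else 0, big.mark = ","))
}

#' Projected total savings table
#'
#' The headline summary: lowest and highest tangible, intangible and total
#' cost savings per crime category and overall, for the database-lifetime
#' and annual scopes.
#'
#' @param config A `figg_config`.
#' @return A tibble with columns `scope`, `category`, `setting`,
#'   `tangible`, `intangible`, `total` (USD), categories followed by a
#'   `total` row per scope/setting.
#' @examples
#' render_table5(default_config())
#' @export
render_table5 <- function(config) {
  res <- static_analysis(config, settings = c("low", "high"))
  per_cat <- res |>
    filter(.data$pool == "combined") |>
    select(all_of(c("scope", "category", "setting", "tangible", "intangible"))) |>
    mutate(total = .data$tangible + .data$intangible)
  totals <- grand_totals(res) |>
    mutate(category = "total", .after = "scope")
  bind_rows(per_cat, totals) |>
    arrange(desc(.data$scope), .data$category != "total", .data$setting)
}

#' Projected additional annual cost table
#'
#' Budget lines (casework and database reagents, amortised instruments,
#' robots, validation, miscellaneous) and annual totals for each cost
#' scenario.
#'
#' @param config A `figg_config`.
#' @return A tibble of annualised lines with per-scenario `total` rows.
#' @examples
#' render_table6(default_config())
#' @export
render_table6 <- function(config) {
  lines <- budget_lines(config$costs$budget)
  totals <- annual_budget(config$costs$budget) |>
    mutate(name = "total_per_year", total_cost = NA_real_,
           amortization_years = NA_real_)
  bind_rows(lines, totals) |>
    arrange(.data$scenario)
}

#' Projected cost per investigative lead table
#'
#' Pairs the high budget with the low upload-increase/lead-rate endpoint
#' (worst case) and the low budget with the high endpoints (best case),
#' mirroring the published projection layout.
#'
#' @param config A `figg_config`.
#' @return A tibble with sample counts, lead counts (display-rounded),
#'   annual cost and cost per lead.
#' @examples
#' render_table7(default_config())
#' @export
render_table7 <- function(config) {
  table7_scenarios(config) |>
    mutate(
      n_samples = round(.data$samples_per_year * (1 + .data$upload_increase)),
      leads_per_year = round(.data$samples_per_year * (1 + .data$upload_increase) *
                               .data$lead_rate),
      cost_per_lead = cost_per_lead(.data$cost_per_year, .data$samples_per_year,
                                    .data$upload_increase, .data$lead_rate)
    ) |>
    select(all_of(c("samples_per_year", "upload_increase", "n_samples",
                    "lead_rate", "leads_per_year", "cost_per_year",
                    "cost_per_lead")))
}

config_fingerprint <- function(config, seed = NULL) {
  payload <- list(
    database = config$database, murder = config$murder,
    categories = as.data.frame(config$categories),
    costs = lapply(config$costs, function(x) if (is_tibble(x)) as.data.frame(x) else x),
    seed = seed
  )
  rlang::hash(payload)
}

#' Build (and optionally write) a full report bundle
#'
#' Runs the static bounding analysis, the Monte Carlo simulation with
#' summaries, tornado sensitivity for each key outcome, and the cost
#' tables, stamping every table with a fingerprint of the exact
#' configuration and seed that produced it so any emitted file can be
#' regenerated bit-identically.
#'
#' @param config A `figg_config`.
#' @param seed Integer seed for the simulation.
#' @param n_trials Monte Carlo trials.
#' @param variant Model variant, as in [run_trials()].
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV and the summary as JSON.
#' @return A `figg_report` list: `fingerprint`, `static`, `totals`,
#'   `simulation_summary`, `tornado` (list by outcome), `table5`, `table6`,
#'   `table7`, `provenance`.
#' @export
cba_report <- function(config, seed = 1L, n_trials = 1000,
                       variant = c("annual_uploads", "total_cases"),
                       out_dir = NULL) {
  variant <- arg_match(variant)
  fp <- config_fingerprint(config, seed)
  static <- static_analysis(config)
  sim <- run_trials(config, n_trials = n_trials, seed = seed, variant = variant)
  summ <- summarize_simulation(sim)
  torn <- lapply(setNames(nm = c("victims", "tangible", "intangible")),
                 function(oc) tornado(config, outcome = oc, variant = variant))
  bundle <- structure(
    list(
      fingerprint = fp,
      static = static,
      totals = grand_totals(static),
      simulation_summary = summ,
      tornado = torn,
      table5 = render_table5(config),
      table6 = render_table6(config),
      table7 = render_table7(config),
      provenance = list(
        package_version = as.character(utils::packageVersion("figgcba")),
        seed = seed, n_trials = n_trials, variant = variant
      )
    ),
    class = "figg_report"
  )
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits each table as CSV (with the config fingerprint in the file name
#' stem kept in `fingerprint.txt`) plus the simulation summary and
#' provenance as JSON.
#'
#' @param bundle A `figg_report` from [cba_report()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "figg_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$fingerprint, file.path(out_dir, "fingerprint.txt"))
  tables <- list(
    static = bundle$static, totals = bundle$totals,
    table5 = bundle$table5, table6 = bundle$table6, table7 = bundle$table7,
    mc_stats = bundle$simulation_summary$stats
  )
  for (nm in names(bundle$tornado)) {
    tables[[paste0("tornado_", nm)]] <- as_tibble(bundle$tornado[[nm]])
  }
  for (nm in names(tables)) {
    write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = bundle$provenance, fingerprint = bundle$fingerprint,
         stats = bundle$simulation_summary$stats),
    file.path(out_dir, "simulation_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.figg_report <- function(x, ...) {
  cat("<figg_report>", x$fingerprint, "\n")
  cat("  trials:", x$provenance$n_trials, "| seed:", x$provenance$seed,
      "| variant:", x$provenance$variant, "\n")
  print(x$totals)
  invisible(x)
}
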