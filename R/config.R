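#' Load a scenario configuration
#'
#' A configuration is a single JSON document with four sections:
#' `database` (national DNA index counts: total forensic profiles, lifetime
#' hits, annual uploads, sexual-assault-kit tallies, funding bounds),
#' `murder` (reported murders per year, clearance rate, projection horizon),
#' `categories` (one row per crime category x parameter, each row a
#' distribution specification, see [dist_spec()]), and `costs` (reagent
#' specifications, annual budget lines, caseload assumptions).
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `figg_config` object: a list with elements
#'   `database` (named list), `murder` (named list), `categories` (tibble)
#'   and `costs` (list of tibbles and named lists).
#' @seealso [save_config()], [default_config()], [validate_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("failed to parse config '", path, "': ", conditionMessage(e)))
  )
  cfg <- new_config(raw)
  problems <- validate_config(cfg)
  if (length(problems)) {
    abort(paste0("invalid config '", path, "':\n  ", paste(problems, collapse = "\n  ")))
  }
  cfg
}

new_config <- function(raw) {
  cats <- as_tibble(raw$categories)
  if (nrow(cats) == 0) {
    cats <- empty_categories()
  } else {
    num_cols <- intersect(c("low", "mode", "high"), names(cats))
    cats <- mutate(cats, across(all_of(num_cols), as.numeric))
    if (!"proportion" %in% names(cats)) cats$proportion <- FALSE
    cats$proportion[is.na(cats$proportion)] <- FALSE
  }
  costs <- raw$costs
  costs$reagents <- coerce_reagents(as_tibble(costs$reagents))
  costs$budget <- coerce_budget(as_tibble(costs$budget))
  if (!is.null(costs$instruments)) costs$instruments <- as_tibble(costs$instruments)
  structure(
    list(
      database = lapply(raw$database, as.numeric),
      murder = lapply(raw$murder, as.numeric),
      categories = cats,
      costs = costs
    ),
    class = "figg_config"
  )
}

coerce_budget <- function(tbl) {
  if (nrow(tbl) == 0) {
    return(tibble(scenario = character(), name = character(),
                  total_cost = numeric(), amortization_years = numeric()))
  }
  mutate(tbl, across(all_of(c("total_cost", "amortization_years")), as.numeric))
}

coerce_reagents <- function(tbl) {
  cols <- c("library_kit_cost", "library_kit_size", "per_library_override",
            "run_kit_cost", "plexity")
  if (nrow(tbl) == 0) {
    return(tibble(name = character(), library_kit_cost = numeric(),
                  library_kit_size = numeric(), per_library_override = numeric(),
                  run_kit_cost = numeric(), plexity = numeric()))
  }
  for (col in cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  tbl
}

#' @export
print.figg_config <- function(x, ...) {
  cat("<figg_config>\n")
  cat("  categories:", paste(unique(x$categories$category), collapse = ", "), "\n")
  cat("  database: total profiles", format(x$database$total_forensic_profiles, big.mark = ","),
      "| lifetime hits", format(x$database$lifetime_hits, big.mark = ","), "\n")
  cat("  budget lines:", nrow(x$costs$budget), "| reagent specs:", nrow(x$costs$reagents), "\n")
  invisible(x)
}

#' Write a configuration back to JSON
#'
#' The emitted file reloads to an equal configuration (round trip is
#' identity), so edited scenarios can be saved and shared.
#'
#' @param config A `figg_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "figg_config"))
  payload <- list(
    database = config$database,
    murder = config$murder,
    categories = as.data.frame(config$categories),
    costs = lapply(config$costs, function(x) if (is_tibble(x)) as.data.frame(x) else x)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' The packaged default configuration
#'
#' Encodes the published inputs the package reproduces: national DNA index
#' and sexual-assault-kit statistics, the per-category parameter ranges
#' (tangible/intangible cost per case, upload increase, upload ratio,
#' category share, annual case totals, investigative lead rate,
#' recidivism/victim-reduction rate, investigation labor), the murder
#' front-end (reported murders, clearance rate, ten-year horizon), and the
#' cost model's reagent kits, instrument purchases and annual budget lines.
#'
#' @return A `figg_config` object.
#' @examples
#' cfg <- default_config()
#' cfg$database$total_forensic_profiles
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.json", package = "figgcba")
  if (!nzchar(path)) abort("packaged default_config.json not found")
  load_config(path)
}

category_parameters <- c(
  "tangible_cost", "intangible_cost", "upload_increase", "upload_ratio",
  "category_share", "total_cases", "lead_rate", "reduction_rate",
  "extra_hours", "police_hourly_rate"
)

#' Validate a configuration
#'
#' Checks every structural invariant: distribution bounds
#' (`low <= mode <= high`, proportions inside \[0, 1\]), database count
#' orderings (`lifetime_hits <= total_forensic_profiles`, the
#' sexual-assault-kit chain `serial hits <= hits <= uploaded <= completed`),
#' murder scalars, reagent specifications (either a kit cost/size pair or a
#' flat per-library price, positive plexity) and budget lines
#' (non-negative cost, amortization of at least one year). Each problem is
#' reported with the path of the offending field.
#'
#' @param config A `figg_config` object (or list shaped like one).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  note <- function(msg) problems[[length(problems) + 1L]] <<- msg

  db <- config$database
  need <- c("total_forensic_profiles", "lifetime_hits", "annual_uploads",
            "saki_completed_kits", "saki_uploaded", "saki_hits",
            "saki_serial_hits", "funding_low", "funding_high")
  missing <- setdiff(need, names(db))
  if (length(missing)) note(paste0("database: missing field(s) ", paste(missing, collapse = ", ")))
  if (all(c("lifetime_hits", "total_forensic_profiles") %in% names(db)) &&
      db$lifetime_hits > db$total_forensic_profiles) {
    note("database.lifetime_hits: exceeds total_forensic_profiles")
  }
  if (all(c("saki_serial_hits", "saki_hits", "saki_uploaded", "saki_completed_kits") %in% names(db))) {
    chain <- c(db$saki_serial_hits, db$saki_hits, db$saki_uploaded, db$saki_completed_kits)
    if (is.unsorted(chain)) note("database.saki_*: requires serial_hits <= hits <= uploaded <= completed_kits")
  }

  mu <- config$murder
  if (is.null(mu$clearance_rate) || mu$clearance_rate < 0 || mu$clearance_rate > 1) {
    note("murder.clearance_rate: must lie in [0, 1]")
  }
  if (is.null(mu$horizon_years) || mu$horizon_years < 1) {
    note("murder.horizon_years: must be >= 1")
  }
  if (is.null(mu$reported_per_year) || mu$reported_per_year < 0) {
    note("murder.reported_per_year: must be non-negative")
  }

  cats <- config$categories
  paths <- paste0("categories[", cats$category, "].", cats$parameter)
  problems <- c(problems, validate_dist(cats, where = paths))
  nonneg <- cats$parameter %in% c("tangible_cost", "intangible_cost", "extra_hours",
                                  "police_hourly_rate", "total_cases")
  bad <- nonneg & cats$low < 0
  if (any(bad)) note(paste0(paths[bad][1], ": must be non-negative"))
  for (cat in unique(cats$category)) {
    have <- cats$parameter[cats$category == cat]
    required <- setdiff(category_parameters, "category_share")
    miss <- setdiff(required, have)
    if (length(miss)) {
      note(paste0("categories[", cat, "]: missing parameter(s) ", paste(miss, collapse = ", ")))
    }
  }

  rg <- config$costs$reagents
  if (!is.null(rg) && nrow(rg)) {
    for (i in seq_len(nrow(rg))) {
      p <- paste0("costs.reagents[", rg$name[[i]], "]")
      has_kit <- !is.na(rg$library_kit_cost[[i]]) && !is.na(rg$library_kit_size[[i]])
      has_flat <- !is.na(rg$per_library_override[[i]])
      if (has_kit == has_flat) {
        note(paste0(p, ": supply exactly one of kit cost/size or per-library price"))
      }
      if (has_kit && rg$library_kit_size[[i]] < 1) note(paste0(p, ".library_kit_size: must be >= 1"))
      if (rg$plexity[[i]] < 1) note(paste0(p, ".plexity: must be >= 1"))
      if (isTRUE(rg$run_kit_cost[[i]] < 0)) note(paste0(p, ".run_kit_cost: must be non-negative"))
    }
  }

  bg <- config$costs$budget
  if (!is.null(bg) && nrow(bg)) {
    bad <- bg$total_cost < 0
    if (any(bad)) note(paste0("costs.budget[", bg$name[bad][1], "].total_cost: must be non-negative"))
    bad <- bg$amortization_years < 1
    if (any(bad)) note(paste0("costs.budget[", bg$name[bad][1], "].amortization_years: must be >= 1"))
  }

  problems
}

#' Look up one category parameter's distribution row
#'
#' @param config A `figg_config`.
#' @param category Category label, e.g. `"sexual_assault"`.
#' @param parameter Parameter name, e.g. `"lead_rate"`.
#' @return A one-row tibble (distribution spec).
#' @keywords internal
config_param <- function(config, category, parameter) {
  row <- filter(config$categories, .data$category == .env$category,
                .data$parameter == .env$parameter)
  if (nrow(row) != 1) {
    abort(paste0("parameter '", parameter, "' not found for category '", category, "'"))
  }
  row
}

param_endpoint <- function(config, category, parameter, setting) {
  row <- config_param(config, category, parameter)
  dist_endpoint(row$kind, row$low, row$mode, row$high, setting)
}
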