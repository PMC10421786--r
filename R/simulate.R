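# Shared chain machinery -------------------------------------------------
#
# Both model variants are multiplicative chains:
#   annual_uploads:  leads = annual_uploads x (1+u) x share x lead_rate
#                    (murder: unsolved/yr x yield x (1+u) x lead_rate)
#   total_cases:     leads = total_cases x share x upload_ratio x (1+u) x lead_rate
# then victims = leads x reduction_rate, savings = victims x cost, and
# investigation cost = leads x hours x hourly rate. chain_spec() captures
# the wiring for one category; eval_chain() evaluates it on scalar
# endpoints or on vectors of sampled values.

chain_spec <- function(config, category, variant = c("annual_uploads", "total_cases")) {
  variant <- arg_match(variant)
  rows <- filter(config$categories, .data$category == .env$category)
  if (nrow(rows) == 0) abort(paste0("no parameters for category '", category, "'"))
  has_share <- "category_share" %in% rows$parameter
  if (variant == "annual_uploads") {
    if (category == "murder") {
      mu <- config$murder
      scale <- mu$reported_per_year * (1 - mu$clearance_rate)
      lead_params <- c("upload_ratio", "upload_increase", "lead_rate")
    } else {
      scale <- config$database$annual_uploads
      lead_params <- c("upload_increase",
                       if (has_share) "category_share",
                       "lead_rate")
    }
  } else {
    scale <- 1
    lead_params <- c("total_cases",
                     if (has_share) "category_share",
                     "upload_ratio", "upload_increase", "lead_rate")
  }
  params <- c(lead_params, "reduction_rate", "tangible_cost", "intangible_cost",
              "extra_hours", "police_hourly_rate")
  inputs <- filter(rows, .data$parameter %in% params)
  missing <- setdiff(params, inputs$parameter)
  if (length(missing)) {
    abort(paste0("category '", category, "' lacks parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  list(category = category, variant = variant, scale = scale,
       lead_params = lead_params, inputs = inputs)
}

# values: named list of numeric vectors, one per input parameter
eval_chain <- function(spec, values) {
  lead_factor <- Reduce(`*`, lapply(spec$lead_params, function(p) {
    v <- values[[p]]
    if (p == "upload_increase") 1 + v else v
  }))
  leads <- spec$scale * lead_factor
  victims <- leads * values$reduction_rate
  tibble(
    leads = leads,
    victims = victims,
    tangible = victims * values$tangible_cost,
    intangible = victims * values$intangible_cost,
    investigation_cost = leads * values$extra_hours * values$police_hourly_rate
  )
}

endpoint_values <- function(spec, setting) {
  vals <- dist_endpoint(spec$inputs$kind, spec$inputs$low, spec$inputs$mode,
                        spec$inputs$high, setting)
  setNames(as.list(vals), spec$inputs$parameter)
}

sampled_values <- function(spec, n) {
  out <- lapply(seq_len(nrow(spec$inputs)), function(i) {
    row <- spec$inputs[i, ]
    dist_sample(n, row$kind, row$low, row$mode, row$high,
                values = if ("values" %in% names(row)) row$values[[1]],
                probs = if ("probs" %in% names(row)) row$probs[[1]])
  })
  setNames(out, spec$inputs$parameter)
}

sim_outcomes <- c("leads", "victims", "tangible", "intangible", "investigation_cost")

# Monte Carlo ------------------------------------------------------------

#' Run Monte Carlo trials of the annual cost-benefit model
#'
#' Each trial independently samples every uncertain input of every crime
#' category from its distribution (see [dist_spec()]) and evaluates the
#' multiplicative chain: investigative leads, prevented victims, tangible
#' and intangible savings, and police investigation cost.
#'
#' Two wirings are available. The default `"annual_uploads"` drives the
#' chain with the yearly upload stream
#' (`annual_uploads x (1+u) x share x lead rate`; murder runs through its
#' unsolved-case front end with the sampled profile yield). The
#' `"total_cases"` variant instead takes the per-category case totals and
#' upload ratios verbatim
#' (`total_cases x share x upload_ratio x (1+u) x lead rate`).
#'
#' @param config A `figg_config`.
#' @param n_trials Number of trials (default 1000).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   results.
#' @param variant `"annual_uploads"` (default) or `"total_cases"`.
#' @return A `figg_simulation` object with elements `trials` (tibble: one
#'   row per trial x category holding every sampled input and every
#'   outcome), `n_trials`, `seed`, `variant`.
#' @examples
#' sim <- run_trials(default_config(), n_trials = 200, seed = 1)
#' tidy(sim)
#' @export
run_trials <- function(config, n_trials = 1000, seed = NULL,
                       variant = c("annual_uploads", "total_cases")) {
  variant <- arg_match(variant)
  if (n_trials < 1) abort("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cats <- unique(config$categories$category)
  trials <- bind_rows(lapply(cats, function(cat) {
    spec <- chain_spec(config, cat, variant)
    vals <- sampled_values(spec, n_trials)
    bind_cols(
      tibble(trial = seq_len(n_trials), category = cat),
      as_tibble(vals),
      eval_chain(spec, vals)
    )
  }))
  structure(
    list(trials = trials, n_trials = n_trials, seed = seed,
         variant = variant, config = config),
    class = "figg_simulation"
  )
}

#' @export
print.figg_simulation <- function(x, ...) {
  cat("<figg_simulation>", x$n_trials, "trials | variant:", x$variant,
      "| seed:", x$seed %||% "none", "\n")
  print(tidy(x), ...)
  invisible(x)
}

combined_trials <- function(trials) {
  trials |>
    group_by(.data$trial) |>
    summarise(across(all_of(sim_outcomes), sum), .groups = "drop") |>
    mutate(category = "combined", .after = "trial")
}

#' Summarise a simulation
#'
#' Descriptive statistics (mean, sd, min, max, 2.5/25/50/75/97.5%
#' quantiles) and equal-width histograms for every outcome of every
#' category plus the per-trial combined totals.
#'
#' @param sim A `figg_simulation` from [run_trials()].
#' @param bins Histogram bin count (equal width over \[min, max\]).
#' @return A `figg_simulation_summary`: list with `stats` (tibble) and
#'   `histograms` (tibble with list-columns `breaks`, `counts`).
#' @examples
#' summarize_simulation(run_trials(default_config(), 200, seed = 1))
#' @export
summarize_simulation <- function(sim, bins = 30) {
  stopifnot(inherits(sim, "figg_simulation"), bins >= 1)
  long <- bind_rows(
    select(sim$trials, all_of(c("trial", "category", sim_outcomes))),
    combined_trials(sim$trials)
  ) |>
    tidyr::pivot_longer(all_of(sim_outcomes),
                        names_to = "outcome", values_to = "value")
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  stats <- long |>
    group_by(.data$category, .data$outcome) |>
    summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      q2.5 = quantile(.data$value, 0.025, names = FALSE),
      q25 = quantile(.data$value, 0.25, names = FALSE),
      median = quantile(.data$value, 0.5, names = FALSE),
      q75 = quantile(.data$value, 0.75, names = FALSE),
      q97.5 = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )
  histograms <- long |>
    group_by(.data$category, .data$outcome) |>
    summarise(hist = list(equal_width_hist(.data$value, bins)), .groups = "drop") |>
    mutate(
      breaks = map(.data$hist, "breaks"),
      counts = map(.data$hist, "counts")
    ) |>
    select(-all_of("hist"))
  structure(
    list(stats = stats, histograms = histograms, n_trials = sim$n_trials,
         seed = sim$seed, variant = sim$variant, bins = bins),
    class = "figg_simulation_summary"
  )
}

equal_width_hist <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(list(breaks = c(rng[1], rng[2]), counts = length(x)))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  list(breaks = breaks, counts = counts)
}

#' @export
print.figg_simulation_summary <- function(x, ...) {
  cat("<figg_simulation_summary>", x$n_trials, "trials | variant:", x$variant, "\n")
  print(x$stats, ...)
  invisible(x)
}
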