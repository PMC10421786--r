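#' Tidy a Monte Carlo simulation
#'
#' One row per category x outcome with the descriptive statistics of the
#' sampled trials (broom convention).
#'
#' @param x A `figg_simulation`.
#' @param ... Passed to [summarize_simulation()] (e.g. `bins`).
#' @return A tibble of summary statistics.
#' @method tidy figg_simulation
#' @export
tidy.figg_simulation <- function(x, ...) {
  summarize_simulation(x, ...)$stats
}

#' One-row summary of a Monte Carlo simulation
#'
#' @param x A `figg_simulation`.
#' @param ... Unused.
#' @return A one-row tibble: trial count, seed, variant and the mean
#'   combined victims, tangible and intangible savings.
#' @method glance figg_simulation
#' @export
glance.figg_simulation <- function(x, ...) {
  comb <- combined_trials(x$trials)
  tibble(
    n_trials = x$n_trials,
    seed = x$seed %||% NA_integer_,
    variant = x$variant,
    mean_victims = mean(comb$victims),
    mean_tangible = mean(comb$tangible),
    mean_intangible = mean(comb$intangible)
  )
}

#' Tidy a tornado analysis
#'
#' @param x A `figg_tornado`.
#' @param ... Unused.
#' @return The underlying tibble (inputs ranked by outcome swing).
#' @method tidy figg_tornado
#' @export
tidy.figg_tornado <- function(x, ...) {
  as_tibble(x)
}
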