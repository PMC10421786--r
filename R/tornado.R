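#' One-at-a-time (tornado) sensitivity analysis
#'
#' For each uncertain input, the deterministic model is evaluated twice —
#' with that input at its low and at its high endpoint, every other input
#' held at its base case — and the rows are ranked by the absolute outcome
#' swing. This is the classic tornado-chart computation; plot the result
#' with [ggplot2::autoplot()].
#'
#' @param config A `figg_config`.
#' @param outcome One of `"leads"`, `"victims"`, `"tangible"`,
#'   `"intangible"`, `"investigation_cost"`.
#' @param category A category label, or `"combined"` to sum the outcome
#'   over all categories (each input still varied one at a time).
#' @param variant Model variant, as in [run_trials()].
#' @return A `figg_tornado` tibble with columns `category`, `parameter`,
#'   `input_low`, `input_high`, `outcome_at_low`, `outcome_at_high`,
#'   `swing`, sorted by descending swing.
#' @examples
#' tornado(default_config(), outcome = "tangible", category = "sexual_assault")
#' @export
tornado <- function(config, outcome = "victims", category = "combined",
                    variant = c("annual_uploads", "total_cases")) {
  variant <- arg_match(variant)
  if (!outcome %in% sim_outcomes) {
    abort(paste0("unknown outcome '", outcome, "'; expected one of ",
                 paste(sim_outcomes, collapse = ", ")))
  }
  cats <- unique(config$categories$category)
  if (!identical(category, "combined")) {
    if (!category %in% cats) abort(paste0("unknown category '", category, "'"))
    cats_eval <- category
  } else {
    cats_eval <- cats
  }
  specs <- setNames(lapply(cats_eval, chain_spec, config = config, variant = variant),
                    cats_eval)
  base_vals <- lapply(specs, endpoint_values, setting = "base")
  base_out <- vapply(cats_eval, function(ct) {
    eval_chain(specs[[ct]], base_vals[[ct]])[[outcome]]
  }, numeric(1))

  rows <- list()
  for (ct in cats_eval) {
    spec <- specs[[ct]]
    for (i in seq_len(nrow(spec$inputs))) {
      row <- spec$inputs[i, ]
      out_at <- function(value) {
        vals <- base_vals[[ct]]
        vals[[row$parameter]] <- value
        own <- eval_chain(spec, vals)[[outcome]]
        own + sum(base_out[setdiff(cats_eval, ct)])
      }
      lo <- out_at(row$low)
      hi <- out_at(row$high)
      rows[[length(rows) + 1L]] <- tibble(
        category = ct, parameter = row$parameter,
        input_low = row$low, input_high = row$high,
        outcome_at_low = lo, outcome_at_high = hi,
        swing = abs(hi - lo)
      )
    }
  }
  out <- if (length(rows)) arrange(bind_rows(rows), desc(.data$swing)) else {
    tibble(category = character(), parameter = character(),
           input_low = numeric(), input_high = numeric(),
           outcome_at_low = numeric(), outcome_at_high = numeric(),
           swing = numeric())
  }
  structure(out, class = c("figg_tornado", class(out)),
            outcome = outcome, target_category = category,
            baseline = sum(base_out))
}
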