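#' Histograms of simulated outcomes
#'
#' Facetted histograms of the per-trial outcome distributions, the usual
#' companion to a probabilistic cost-benefit run.
#'
#' @param object A `figg_simulation`.
#' @param outcome Outcome to plot (default `"victims"`).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sim <- run_trials(default_config(), 200, seed = 1)
#' ggplot2::autoplot(sim, outcome = "tangible")
#' @method autoplot figg_simulation
#' @export
autoplot.figg_simulation <- function(object, outcome = "victims", bins = 30, ...) {
  if (!outcome %in% sim_outcomes) abort(paste0("unknown outcome '", outcome, "'"))
  dat <- bind_rows(
    select(object$trials, all_of(c("trial", "category", sim_outcomes))),
    combined_trials(object$trials)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[outcome]])) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::labs(
      x = outcome, y = "trials",
      title = paste0("Simulated annual ", outcome, " (", object$n_trials, " trials)")
    ) +
    ggplot2::theme_minimal()
}

#' Tornado chart
#'
#' Horizontal bars spanning each input's low/high outcome, ranked by
#' swing, around the all-base-case outcome.
#'
#' @param object A `figg_tornado` from [tornado()].
#' @param top Show only the `top` largest swings (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(tornado(default_config(), outcome = "victims"))
#' @method autoplot figg_tornado
#' @export
autoplot.figg_tornado <- function(object, top = Inf, ...) {
  dat <- as_tibble(object) |>
    mutate(label = paste(.data$category, .data$parameter, sep = ": ")) |>
    arrange(desc(.data$swing))
  if (is.finite(top)) dat <- dat[seq_len(min(top, nrow(dat))), ]
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_at_low,
                                       xend = .data$outcome_at_high,
                                       yend = .data$label),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "baseline"), linetype = 2) +
    ggplot2::labs(
      x = attr(object, "outcome"), y = NULL,
      title = paste0("One-at-a-time sensitivity: ", attr(object, "outcome"),
                     " (", attr(object, "target_category"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
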