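#' Specify an uncertain model input
#'
#' Uncertain inputs to the cost-benefit model are described by a small set of
#' distribution families: `triangular(low, mode, high)` for inputs with a
#' stated base case, `uniform(low, high)` for inputs known only as a range,
#' `point(value)` for fixed inputs, and `discrete(values, probs)` for
#' few-valued inputs (used mainly by the enumeration oracle).
#'
#' @param kind One of `"triangular"`, `"uniform"`, `"point"`, `"discrete"`.
#' @param low,high Support bounds. For `"point"`, both equal the value.
#' @param mode Most-likely value; required for `"triangular"` (it is the
#'   table's base-case column and may sit on either bound, giving a
#'   degenerate but valid triangle). For `"uniform"` it is stored as the
#'   midpoint, for `"point"` as the value.
#' @param values,probs Support and probabilities for `"discrete"`.
#'
#' @return A one-row tibble with columns `kind`, `low`, `mode`, `high` (and,
#'   for discrete specs, list-columns `values`, `probs`).
#' @examples
#' dist_spec("triangular", low = 5000, mode = 7419, high = 10000)
#' dist_spec("uniform", low = 0.135, high = 0.20)
#' @export
dist_spec <- function(kind = c("triangular", "uniform", "point", "discrete"),
                      low = NULL, high = NULL, mode = NULL,
                      values = NULL, probs = NULL) {
  kind <- arg_match(kind)
  if (kind == "discrete") {
    stopifnot(length(values) >= 1, length(values) == length(probs))
    probs <- probs / sum(probs)
    out <- tibble(
      kind = kind, low = min(values), mode = values[[which.max(probs)]],
      high = max(values), values = list(values), probs = list(probs)
    )
    return(out)
  }
  if (kind == "point") {
    value <- low %||% mode %||% high
    low <- high <- mode <- value
  }
  if (kind == "uniform") mode <- (low + high) / 2
  spec <- tibble(kind = kind, low = low, mode = mode, high = high)
  problems <- validate_dist(spec)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  spec
}

#' Validate distribution rows
#'
#' Checks the invariants of a table of distribution specifications:
#' finiteness, `low <= mode <= high`, `low == mode == high` for point
#' specs, and, where a row is flagged as a proportion, support inside
#' \[0, 1\].
#'
#' @param tbl A tibble with columns `kind`, `low`, `mode`, `high`, and
#'   optionally a logical `proportion` column.
#' @param where Optional character vector of row labels used to build
#'   field paths in messages.
#' @return A character vector of problems (empty when valid).
#' @export
validate_dist <- function(tbl, where = NULL) {
  where <- where %||% paste0("row ", seq_len(nrow(tbl)))
  problems <- character()
  note <- function(i, msg) {
    problems[[length(problems) + 1L]] <<- paste0(where[[i]], ": ", msg)
  }
  has_prop <- "proportion" %in% names(tbl)
  for (i in seq_len(nrow(tbl))) {
    k <- tbl$kind[[i]]
    lo <- tbl$low[[i]]; mo <- tbl$mode[[i]]; hi <- tbl$high[[i]]
    if (!k %in% c("triangular", "uniform", "point", "discrete")) {
      note(i, paste0("unknown distribution kind '", k, "'"))
      next
    }
    if (!all(is.finite(c(lo, mo, hi)))) {
      note(i, "non-finite bound")
      next
    }
    if (lo > hi) note(i, paste0("low (", lo, ") exceeds high (", hi, ")"))
    if (k == "triangular" && (mo < lo || mo > hi)) {
      note(i, paste0("mode (", mo, ") outside [", lo, ", ", hi, "]"))
    }
    if (k == "point" && !(lo == mo && mo == hi)) {
      note(i, "point spec requires low == mode == high")
    }
    if (has_prop && isTRUE(tbl$proportion[[i]]) && (lo < 0 || hi > 1)) {
      note(i, paste0("proportion support [", lo, ", ", hi, "] outside [0, 1]"))
    }
  }
  problems
}

#' Analytic mean of a distribution specification
#'
#' Vectorised over parallel `kind`/`low`/`mode`/`high` vectors. Triangular
#' mean is `(low + mode + high) / 3`; uniform mean is the midpoint; a point
#' spec returns its value.
#'
#' @inheritParams dist_sample
#' @return Numeric vector of means.
#' @examples
#' dist_mean("triangular", 5000, 7419, 10000) # 7473
#' @export
dist_mean <- function(kind, low, mode, high) {
  out <- numeric(length(kind))
  tri <- kind == "triangular"
  out[tri] <- (low[tri] + mode[tri] + high[tri]) / 3
  uni <- kind == "uniform"
  out[uni] <- (low[uni] + high[uni]) / 2
  pt <- kind == "point"
  out[pt] <- low[pt]
  bad <- !(tri | uni | pt)
  if (any(bad)) abort(paste0("dist_mean: unsupported kind '", kind[bad][1], "'"))
  out
}

#' Draw from a distribution specification
#'
#' Sampling is driven by `stats::runif()` so that a single `set.seed()`
#' upstream makes whole simulations reproducible. Triangular draws use the
#' closed-form two-branch inverse CDF; degenerate triangles (mode on a
#' bound, or zero-width support) are handled exactly.
#'
#' @param n Number of draws.
#' @param kind,low,mode,high Scalar distribution fields (see [dist_spec()]).
#' @param values,probs Support and probabilities when `kind = "discrete"`.
#' @return Numeric vector of length `n`, all values within `[low, high]`.
#' @export
dist_sample <- function(n, kind, low, mode, high, values = NULL, probs = NULL) {
  switch(kind,
    point = rep_len(low, n),
    uniform = runif(n, low, high),
    triangular = {
      if (high == low) return(rep_len(low, n))
      u <- runif(n)
      fc <- (mode - low) / (high - low)
      ifelse(
        u < fc,
        low + sqrt(u * (high - low) * (mode - low)),
        high - sqrt((1 - u) * (high - low) * (high - mode))
      )
    },
    discrete = {
      u <- runif(n)
      idx <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
      values[idx]
    },
    abort(paste0("dist_sample: unsupported kind '", kind, "'"))
  )
}

#' Endpoint of a distribution under a deterministic setting
#'
#' The static bounding model evaluates each input at `"low"`, `"base"`
#' (the mode) or `"high"`.
#'
#' @inheritParams dist_sample
#' @param setting `"low"`, `"base"` or `"high"`.
#' @return Numeric vector.
#' @export
dist_endpoint <- function(kind, low, mode, high, setting = c("low", "base", "high")) {
  setting <- arg_match(setting)
  switch(setting, low = low, base = mode, high = high)
}
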