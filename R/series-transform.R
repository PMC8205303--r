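#' First-order differencing
#'
#' Computes the consecutive changes `diff[t] = value[t+1] - value[t]` that
#' turn a nonstationary level series into an approximately stationary
#' difference series. The anchor levels (the observed level preceding each
#' difference) are retained so the transform is exactly invertible.
#'
#' @param series a [level_series()] of length >= 2, no missing values.
#' @return object of class `diff_series`: list with `diffs` (numeric,
#'   length m - 1), `anchors` (the level preceding each diff) and
#'   `timestamps` (the time of each diff's *target* point).
#' @export
first_difference <- function(series) {
  series <- as_level_series(series)
  m <- nrow(series)
  if (m < 2L) {
    stop_model_error("differencing needs at least 2 points")
  }
  v <- series$value
  structure(
    list(
      diffs = v[-1L] - v[-m],
      anchors = v[-m],
      timestamps = series$timestamp[-1L]
    ),
    class = "diff_series"
  )
}

#' @export
print.diff_series <- function(x, ...) {
  cat(sprintf(
    "<diff_series> %d diffs, range [%.4f, %.4f]\n",
    length(x$diffs), min(x$diffs), max(x$diffs)
  ))
  invisible(x)
}

#' Reconstruct levels from predicted differences
#'
#' One-step-ahead reconstruction adds each predicted difference to the
#' *observed* level at the current moment (never to a previous prediction):
#' `level'[t] = diff'[t] + level[t]`. Passing a single anchor level instead
#' performs cumulative reconstruction `anchor + cumsum(diffs)`, the exact
#' inverse of [first_difference()].
#'
#' @param predicted_diffs numeric vector of predicted differences (mg/L),
#'   or difference symbols (converted with [symbol_value()]).
#' @param observed_levels numeric vector of the observed levels each
#'   prediction is added to (same length as `predicted_diffs`), or a single
#'   anchor level for cumulative reconstruction.
#' @return numeric vector of reconstructed levels.
#' @export
reconstruct <- function(predicted_diffs, observed_levels) {
  if (is.character(predicted_diffs)) {
    predicted_diffs <- symbol_value(predicted_diffs)
  }
  if (inherits(observed_levels, "level_series")) {
    observed_levels <- observed_levels$value
  }
  if (length(observed_levels) == 1L) {
    return(observed_levels + cumsum(predicted_diffs))
  }
  if (length(observed_levels) != length(predicted_diffs)) {
    stop_model_error(sprintf(
      "alignment mismatch: %d predicted diffs vs %d observed levels",
      length(predicted_diffs), length(observed_levels)
    ))
  }
  observed_levels + predicted_diffs
}

# Canonical fixed-precision text form of a difference symbol. Rounds
# half-to-even, then collapses -0 and +0 into one symbol.
format_symbol <- function(x, decimals) {
  r <- round(x, decimals)
  r[r == 0] <- 0 # normalize -0
  sprintf("%.*f", decimals, r)
}

# Deterministic numeric ordering of symbol strings (locale-independent);
# falls back to byte order for non-numeric symbols.
symbol_order <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) order(x, method = "radix") else order(v)
}

sym_sort <- function(x) {
  u <- unique(x)
  u[symbol_order(u)]
}

#' Discretize differences into category symbols
#'
#' The model treats the possible values of the difference series as a
#' finite set of categories. Discretization rounds each difference
#' half-to-even to `decimals` places and renders it as a fixed-precision
#' string symbol, so two raw differences that round to the same value
#' compare equal as categories. The default of 2 decimals matches a
#' typical 0.01 mg/L sensor resolution.
#'
#' @param diffs a `diff_series` from [first_difference()] or a numeric
#'   vector of differences.
#' @param decimals non-negative integer rounding precision.
#' @return character vector of symbols; the set of distinct symbols is the
#'   alphabet.
#' @export
#' @examples
#' discretize(c(0.104, 0.096), decimals = 1) # both "0.1"
discretize <- function(diffs, decimals = 2L) {
  if (inherits(diffs, "diff_series")) diffs <- diffs$diffs
  if (!is.numeric(diffs)) stop_model_error("diffs must be numeric")
  if (anyNA(diffs)) stop_model_error("diffs contain missing values")
  if (!is.numeric(decimals) || length(decimals) != 1L || decimals < 0 ||
    decimals != floor(decimals)) {
    stop_model_error("decimals must be a non-negative integer")
  }
  format_symbol(diffs, as.integer(decimals))
}

#' Numeric value of difference symbols
#'
#' @param symbols character vector of symbols from [discretize()].
#' @return numeric vector.
#' @export
symbol_value <- function(symbols) {
  as.numeric(symbols)
}
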