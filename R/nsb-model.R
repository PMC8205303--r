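#' @name nsb_model
#' @title The enhanced semi-naive Bayes difference forecaster
#'
#' @description
#' The model treats each possible (rounded) value of the first-order
#' difference series as a category. Every attribute position in a window
#' can act as the "super-parent" the other attributes depend on; the
#' posterior for a candidate class \eqn{y} given an attribute window
#' \eqn{x_1 \ldots x_d} (with \eqn{d = L - 1}) is scored as
#' \deqn{P(y \mid x) \propto \sum_{i=1}^{d} \hat P(y, x_i)
#'   \prod_{j=1}^{d} \hat P(x_j \mid y, x_i)}
#' with Laplace-smoothed estimates
#' \deqn{\hat P(y, x_i) = \frac{|D_{y,x_i}| + 1}{|D| + N A}, \qquad
#'   \hat P(x_j \mid y, x_i) = \frac{|D_{y,x_i,x_j}| + 1}{|D_{y,x_i}| + A}}
#' where \eqn{|D|} is the number of training samples, \eqn{N} the number
#' of retained classes and \eqn{A} the training alphabet size (every
#' attribute position shares the one difference alphabet, so all
#' per-position value-set cardinalities equal \eqn{A}). The inner product
#' deliberately runs over all \eqn{j}, including \eqn{j = i}; classic AODE
#' excludes the super-parent from its own product, this model does not.
#'
#' Because the model is a set of integer count tables, it supports exact
#' incremental updates: counting new samples on top of an existing model
#' is identical to refitting on the pooled data.
NULL

KEY_SEP <- "|"

pair_key <- function(y, i, xi) paste(y, i, xi, sep = KEY_SEP)
triple_key <- function(y, i, xi, j, xj) paste(y, i, xi, j, xj, sep = KEY_SEP)

count_keys <- function(keys) {
  tab <- table(keys)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[sort(names(out), method = "radix")]
}

lookup_counts <- function(counts, keys) {
  v <- counts[keys]
  v[is.na(v)] <- 0L
  as.integer(v)
}

# One pass over a sample matrix -> pair and triple count tables.
tabulate_counts <- function(mat, L) {
  d <- L - 1L
  labels <- mat[, L]
  pair_keys <- character(0)
  triple_keys <- character(0)
  for (i in seq_len(d)) {
    pair_keys <- c(pair_keys, pair_key(labels, i, mat[, i]))
    for (j in seq_len(d)) {
      triple_keys <- c(triple_keys, triple_key(labels, i, mat[, i], j, mat[, j]))
    }
  }
  list(pair = count_keys(pair_keys), triple = count_keys(triple_keys))
}

#' Fit the semi-naive Bayes model from windowed samples
#'
#' Populates the count tables in a single pass over the (already
#' gamma-filtered) sample set. The retained classes are the distinct
#' labels; the alphabet is the full training symbol set, which also fixes
#' the per-position cardinalities used by the Laplace denominators.
#'
#' @param samples an `nsb_samples`, typically from
#'   [build_samples()] then [filter_by_frequency()].
#' @param gamma the frequency threshold the samples were filtered with
#'   (recorded in the model; default 0).
#' @param decimals the rounding precision the symbols were discretized
#'   with (recorded in the model; default 2).
#' @return object of class `nsb_model`.
#' @seealso [nsb_train()] for the level-series-to-model pipeline.
#' @export
nsb_fit <- function(samples, gamma = 0, decimals = 2L) {
  stopifnot(inherits(samples, "nsb_samples"))
  if (samples$n_samples < 1L) {
    stop_model_error("empty model: no training samples")
  }
  L <- samples$window_length
  counts <- tabulate_counts(samples$samples, L)
  structure(
    list(
      version = "1.0",
      window_length = L,
      gamma = gamma,
      decimals = as.integer(decimals),
      alphabet = samples$alphabet,
      classes = sym_sort(names(samples$class_freq)),
      class_counts = samples$class_freq,
      total = samples$n_samples,
      pair_counts = counts$pair,
      triple_counts = counts$triple
    ),
    class = "nsb_model"
  )
}

#' @export
print.nsb_model <- function(x, ...) {
  cat(sprintf(
    "<nsb_model> L = %d, gamma = %g, decimals = %d\n  %d training samples, alphabet size %d, %d retained classes\n",
    x$window_length, x$gamma, x$decimals, x$total,
    length(x$alphabet), length(x$classes)
  ))
  invisible(x)
}

merge_counts <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- stats::setNames(integer(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[sort(keys, method = "radix")]
}

#' Incrementally update a fitted model with new samples
#'
#' Adds the counts of `new_samples` to the model's tables. The result is
#' table-for-table identical to refitting on the pooled sample set, so a
#' deployed model can absorb new data without regeneration. Symbols not
#' previously seen extend the alphabet (the smoothing denominators grow
#' accordingly), and new labels extend the class set.
#'
#' @param model a fitted `nsb_model`.
#' @param new_samples an `nsb_samples` with the same window length,
#'   discretized at the same precision.
#' @return the updated `nsb_model`.
#' @export
nsb_update <- function(model, new_samples) {
  stopifnot(inherits(model, "nsb_model"), inherits(new_samples, "nsb_samples"))
  if (new_samples$window_length != model$window_length) {
    stop_model_error(sprintf(
      "configuration mismatch: model window length %d vs new samples %d",
      model$window_length, new_samples$window_length
    ))
  }
  if (new_samples$n_samples == 0L) {
    return(model)
  }
  counts <- tabulate_counts(new_samples$samples, model$window_length)
  model$pair_counts <- merge_counts(model$pair_counts, counts$pair)
  model$triple_counts <- merge_counts(model$triple_counts, counts$triple)
  model$class_counts <- merge_counts(model$class_counts, new_samples$class_freq)
  model$class_counts <- model$class_counts[symbol_order(names(model$class_counts))]
  model$classes <- sym_sort(names(model$class_counts))
  model$alphabet <- sym_sort(c(model$alphabet, new_samples$alphabet))
  model$total <- model$total + new_samples$n_samples
  model
}

#' Laplace-smoothed probability estimates
#'
#' `laplace_joint()` estimates the joint probability of class `y` and
#' value `x_i` at attribute position `i`; `laplace_conditional()` the
#' probability of value `x_j` at position `j` given the class and the
#' super-parent value. One pseudo-count per cell guarantees neither is
#' ever zero; with the shared-alphabet cardinalities both families sum
#' exactly to one over their support.
#'
#' @param model a fitted `nsb_model`.
#' @param y class symbol.
#' @param i,j attribute positions in `1 .. L-1`.
#' @param x_i,x_j attribute symbols (zero counts if unseen in training).
#' @return a probability in (0, 1).
#' @export
laplace_joint <- function(model, y, i, x_i) {
  check_position(model, i)
  N <- length(model$classes)
  A <- length(model$alphabet)
  pc <- lookup_counts(model$pair_counts, pair_key(y, i, x_i))
  (pc + 1) / (model$total + N * A)
}

#' @rdname laplace_joint
#' @export
laplace_conditional <- function(model, y, i, x_i, j, x_j) {
  check_position(model, i)
  check_position(model, j)
  A <- length(model$alphabet)
  pc <- lookup_counts(model$pair_counts, pair_key(y, i, x_i))
  tc <- lookup_counts(model$triple_counts, triple_key(y, i, x_i, j, x_j))
  (tc + 1) / (pc + A)
}

check_position <- function(model, i) {
  d <- model$window_length - 1L
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > d || i != floor(i)) {
    stop_model_error(sprintf("attribute position must be in 1..%d", d))
  }
}

as_window <- function(model, window) {
  if (is.numeric(window)) window <- format_symbol(window, model$decimals)
  d <- model$window_length - 1L
  if (length(window) != d) {
    stop_model_error(sprintf(
      "window must hold %d attribute symbols, got %d", d, length(window)
    ))
  }
  window
}

#' Score every retained class for an attribute window
#'
#' Evaluates the averaged super-parent sum for each retained class. The
#' per-super-parent products are accumulated in the log domain and
#' exponentiated before the outer sum (the terms are added, so a pure
#' log-domain evaluation is impossible). Window symbols outside the
#' training alphabet simply contribute zero counts and receive only
#' smoothing mass.
#'
#' @param model a fitted `nsb_model`.
#' @param window `L - 1` difference symbols (character), or numeric
#'   differences which are discretized at the model's precision.
#' @return list with `posterior` (named scores normalized to sum to 1)
#'   and `log_score` (raw log-domain class scores).
#' @export
nsb_score <- function(model, window) {
  window <- as_window(model, window)
  d <- model$window_length - 1L
  classes <- model$classes
  N <- length(classes)
  A <- length(model$alphabet)

  ys <- rep(classes, each = d)
  is <- rep(seq_len(d), times = N)
  xi <- window[is]
  pc <- lookup_counts(model$pair_counts, pair_key(ys, is, xi))
  log_joint <- log(pc + 1) - log(model$total + N * A)

  js <- rep(seq_len(d), times = N * d)
  tkeys <- triple_key(
    rep(ys, each = d), rep(is, each = d), rep(xi, each = d),
    js, window[js]
  )
  tc <- lookup_counts(model$triple_counts, tkeys)
  log_cond_terms <- log(tc + 1) - rep(log(pc + A), each = d)
  log_cond <- colSums(matrix(log_cond_terms, nrow = d))

  terms <- exp(log_joint + log_cond)
  raw <- colSums(matrix(terms, nrow = d))
  names(raw) <- classes
  list(posterior = raw / sum(raw), log_score = log(raw))
}

#' Predict the next difference symbol
#'
#' Argmax of the class scores, with a deterministic tie-break: among
#' classes whose scores are equal (to within 1e-12 relative tolerance),
#' prefer (1) the larger training class frequency, then (2) the smaller
#' absolute symbol value, then (3) the smaller signed value.
#'
#' @inheritParams nsb_score
#' @return a single difference symbol (character).
#' @export
predict_next <- function(model, window) {
  if (length(model$classes) == 0L) {
    stop_model_error("empty model: no retained classes")
  }
  s <- nsb_score(model, window)$posterior
  predict_from_scores(model, s)
}

#' One-step-ahead walk-forward forecast of a level series
#'
#' Forecasts each point of `test_levels` from the observed history only:
#' at each step the attribute window is built from the most recent
#' *observed* differences (discretized at the model's precision), the
#' predicted difference symbol is chosen by maximum posterior, and its
#' value is added to the current observed level. Predictions are never
#' fed back as inputs. The first forecast targets the point after the
#' first `L - 1` test differences, so the forecast length is the number
#' of test differences minus `L - 1`.
#'
#' @param model a fitted `nsb_model`.
#' @param test_levels a [level_series()] of length at least `L + 1`.
#' @return object of class `nsb_forecast`: a data frame with columns
#'   `timestamp` (forecast target time), `observed`, `predicted_diff`,
#'   `predicted_level` and `posterior_score` (normalized posterior of the
#'   chosen class).
#' @export
forecast_series <- function(model, test_levels) {
  test_levels <- as_level_series(test_levels)
  L <- model$window_length
  d <- L - 1L
  k <- nrow(test_levels)
  if (k < L + 1L) {
    stop_model_error(sprintf(
      "test series has %d points; walk-forward forecasting with L = %d needs at least %d",
      k, L, L + 1L
    ))
  }
  dif <- first_difference(test_levels)
  symbols <- discretize(dif$diffs, model$decimals)
  n_diffs <- length(symbols)
  steps <- seq.int(d + 1L, n_diffs) # diff index being predicted
  pred_sym <- character(length(steps))
  post <- numeric(length(steps))
  for (s in seq_along(steps)) {
    t <- steps[s]
    window <- symbols[(t - d):(t - 1L)]
    sc <- nsb_score(model, window)$posterior
    sym <- predict_from_scores(model, sc)
    pred_sym[s] <- sym
    post[s] <- sc[[sym]]
  }
  pred_diff <- symbol_value(pred_sym)
  current_level <- test_levels$value[steps] # level at the current moment
  structure(
    data.frame(
      timestamp = test_levels$timestamp[steps + 1L],
      observed = test_levels$value[steps + 1L],
      predicted_diff = pred_diff,
      predicted_level = reconstruct(pred_diff, current_level),
      posterior_score = post
    ),
    class = c("nsb_forecast", "data.frame")
  )
}

# Tie-break shared between predict_next() and forecast_series() so both
# paths pick the same class from a score vector.
predict_from_scores <- function(model, s) {
  top <- max(s)
  cand <- names(s)[s >= top - 1e-12 * top]
  if (length(cand) > 1L) {
    freq <- lookup_counts(model$class_counts, cand)
    val <- as.numeric(cand)
    cand <- cand[order(-freq, abs(val), val)]
  }
  cand[[1L]]
}

#' @export
print.nsb_forecast <- function(x, ...) {
  cat(sprintf(
    "<nsb_forecast> %d one-step-ahead predictions, %s .. %s\n",
    nrow(x), format(x$timestamp[1L]), format(x$timestamp[nrow(x)])
  ))
  invisible(x)
}

#' Train a model directly from a level series
#'
#' Convenience pipeline: difference, discretize, window, gamma-filter,
#' fit. This is what the CLI's `fit` command runs on the training split.
#'
#' @param series a [level_series()].
#' @param window_length window length `L >= 2`.
#' @param gamma class-frequency threshold in `[0, 1)`.
#' @param decimals discretization precision.
#' @return a fitted `nsb_model`.
#' @export
nsb_train <- function(series, window_length, gamma = 0, decimals = 2L) {
  symbols <- discretize(first_difference(series), decimals)
  samples <- build_samples(symbols, window_length)
  nsb_log(
    "windowed %d symbols into %d samples (alphabet %d, %d classes)",
    length(symbols), samples$n_samples, length(samples$alphabet),
    length(samples$class_freq)
  )
  filtered <- filter_by_frequency(samples, gamma)
  nsb_log(
    "gamma = %g retained %d/%d samples (%d classes)",
    gamma, filtered$n_samples, samples$n_samples, length(filtered$class_freq)
  )
  nsb_fit(filtered, gamma = gamma, decimals = decimals)
}

#' Save and load a model as JSON
#'
#' The model file is a schema-versioned JSON document holding the integer
#' count tables verbatim, with symbols serialized as fixed-precision
#' decimal strings (never float keys), so a save/load round trip
#' preserves every count exactly and reloaded models give identical
#' predictions.
#'
#' @param model a fitted `nsb_model`.
#' @param path file path for the model JSON.
#' @return `nsb_load()` returns the `nsb_model`.
#' @export
nsb_save <- function(model, path) {
  stopifnot(inherits(model, "nsb_model"))
  doc <- list(
    version = model$version,
    window_length = model$window_length,
    gamma = model$gamma,
    decimals = model$decimals,
    alphabet = model$alphabet,
    classes = model$classes,
    class_counts = as.list(model$class_counts),
    total = model$total,
    pair_counts = as.list(model$pair_counts),
    triple_counts = as.list(model$triple_counts)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname nsb_save
#' @export
nsb_load <- function(path) {
  if (!file.exists(path)) {
    stop_io_error(sprintf("model file not found: %s", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version) || !identical(doc$version, "1.0")) {
    stop_io_error(sprintf("unsupported model schema version in %s", path))
  }
  to_counts <- function(x) {
    stats::setNames(vapply(x, function(v) as.integer(v), integer(1)), names(x))
  }
  structure(
    list(
      version = doc$version,
      window_length = as.integer(doc$window_length),
      gamma = as.numeric(doc$gamma),
      decimals = as.integer(doc$decimals),
      alphabet = vapply(doc$alphabet, as.character, character(1)),
      classes = vapply(doc$classes, as.character, character(1)),
      class_counts = to_counts(doc$class_counts),
      total = as.integer(doc$total),
      pair_counts = to_counts(doc$pair_counts),
      triple_counts = to_counts(doc$triple_counts)
    ),
    class = "nsb_model"
  )
}
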