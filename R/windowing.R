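#' Build sliding-window samples from a symbol sequence
#'
#' Slides a window of length `L` with stride 1 over the difference-symbol
#' sequence. In each window the last element is the class label (the
#' difference to predict) and the preceding `L - 1` elements are the
#' attributes, so a sequence of `Z` symbols yields `Z - L + 1` samples.
#'
#' @param symbols character vector of difference symbols
#'   (see [discretize()]).
#' @param window_length integer `L >= 2`.
#' @return object of class `nsb_samples`: list with `samples` (character
#'   matrix, one row per window, `L` columns, label last), `window_length`,
#'   `alphabet` (distinct symbols in numeric order), `class_freq` (named
#'   count of labels) and `n_samples`.
#' @export
#' @examples
#' build_samples(c("a", "b", "c", "d"), window_length = 3)
build_samples <- function(symbols, window_length) {
  L <- window_length
  if (!is.numeric(L) || length(L) != 1L || L < 2L || L != floor(L)) {
    stop_model_error("window_length must be an integer >= 2")
  }
  L <- as.integer(L)
  if (!is.character(symbols)) {
    stop_model_error("symbols must be a character vector (see discretize())")
  }
  Z <- length(symbols)
  if (Z < L) {
    stop_model_error(sprintf(
      "symbol sequence of length %d is shorter than the window length %d", Z, L
    ))
  }
  idx <- embed(seq_len(Z), L)[, L:1, drop = FALSE]
  mat <- matrix(symbols[idx], ncol = L)
  new_samples(mat, L, alphabet = sort_alphabet(symbols))
}

sort_alphabet <- function(symbols) sym_sort(symbols)

new_samples <- function(mat, L, alphabet) {
  labels <- mat[, L]
  freq <- table(labels)
  cf <- stats::setNames(as.integer(freq), names(freq))
  cf <- cf[symbol_order(names(cf))]
  structure(
    list(
      samples = mat,
      window_length = L,
      alphabet = alphabet,
      class_freq = cf,
      n_samples = nrow(mat)
    ),
    class = "nsb_samples"
  )
}

#' @export
print.nsb_samples <- function(x, ...) {
  cat(sprintf(
    "<nsb_samples> %d samples, window length %d (%d attributes), alphabet size %d, %d classes\n",
    x$n_samples, x$window_length, x$window_length - 1L,
    length(x$alphabet), length(x$class_freq)
  ))
  invisible(x)
}

#' Filter samples by class-label frequency
#'
#' Noisy sensors produce rare, outlying difference categories. Rather than
#' editing the raw series, the model drops training windows whose *label*
#' is rare: a sample is retained iff its label's relative frequency --
#' measured once, on the input set -- is strictly larger than `gamma`.
#' Attribute values are not filtered; rare symbols remain usable as
#' attributes (Laplace smoothing handles them), and the alphabet is kept
#' intact. Sample order is preserved.
#'
#' This is a single-pass operator: frequencies come from the operator's own
#' input, so re-applying it to its output with the same `gamma` may remove
#' more samples (frequencies are re-measured on the smaller set).
#'
#' @param samples an `nsb_samples` from [build_samples()].
#' @param gamma frequency threshold in `[0, 1)`; `gamma = 0` retains
#'   everything.
#' @return filtered `nsb_samples` with class frequencies recomputed on the
#'   retained set.
#' @export
filter_by_frequency <- function(samples, gamma) {
  stopifnot(inherits(samples, "nsb_samples"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1) {
    stop_model_error("gamma must lie in [0, 1)")
  }
  L <- samples$window_length
  labels <- samples$samples[, L]
  n <- length(labels)
  freq <- table(labels) / n
  keep <- as.vector(freq[labels]) > gamma
  if (!any(keep)) {
    stop_model_error(sprintf(
      "empty model: frequency threshold gamma = %g removed every training sample (maximum class frequency is %.6f)",
      gamma, max(freq)
    ))
  }
  new_samples(samples$samples[keep, , drop = FALSE], L, alphabet = samples$alphabet)
}

# Row-bind two sample sets (used by the incremental-update identity);
# alphabets are merged.
combine_samples <- function(a, b) {
  stopifnot(inherits(a, "nsb_samples"), inherits(b, "nsb_samples"))
  if (a$window_length != b$window_length) {
    stop_model_error("cannot combine sample sets with different window lengths")
  }
  new_samples(
    rbind(a$samples, b$samples), a$window_length,
    alphabet = sym_sort(c(a$alphabet, b$alphabet))
  )
}

# Split a sample set by row indices; used in tests.
subset_samples <- function(samples, idx) {
  new_samples(
    samples$samples[idx, , drop = FALSE],
    samples$window_length,
    alphabet = samples$alphabet
  )
}
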