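# Independent brute-force scorer: loops over the raw sample list and
# recomputes every count inside the averaged super-parent sum. Shares no
# code with the table-driven implementation it cross-checks.
oracle_scores <- function(mat, alphabet, window) {
  L <- ncol(mat)
  d <- L - 1L
  labels <- mat[, L]
  classes <- unique(labels)
  classes <- classes[order(as.numeric(classes))]
  A <- length(alphabet)
  N <- length(classes)
  total <- nrow(mat)
  raw <- vapply(classes, function(y) {
    s <- 0
    for (i in seq_len(d)) {
      Dyxi <- sum(labels == y & mat[, i] == window[i])
      term <- (Dyxi + 1) / (total + N * A)
      for (j in seq_len(d)) {
        Dyxixj <- sum(labels == y & mat[, i] == window[i] & mat[, j] == window[j])
        term <- term * (Dyxixj + 1) / (Dyxi + A)
      }
      s <- s + term
    }
    s
  }, numeric(1))
  names(raw) <- classes
  raw / sum(raw)
}

# Random tiny instance over a numeric symbol pool: a symbol sequence, a
# window length, and a probe window that may contain unseen symbols.
random_toy <- function() {
  pool <- c("-0.10", "0.00", "0.10", "0.20")
  n_pool <- sample(2:4, 1)
  syms <- pool[seq_len(n_pool)]
  L <- sample(2:4, 1)
  n_samp <- sample(1:8, 1)
  list(
    symbols = sample(syms, n_samp + L - 1L, replace = TRUE),
    L = L,
    window = sample(pool, L - 1L, replace = TRUE)
  )
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
sample_excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3

# 3-state transition matrix used by the Markov recovery checks: strong
# diagonal so the Bayes-optimal rule is "repeat the current symbol".
markov_P3 <- matrix(
  c(
    0.70, 0.20, 0.10,
    0.15, 0.70, 0.15,
    0.10, 0.20, 0.70
  ),
  nrow = 3, byrow = TRUE
)
markov_symbols3 <- c("-0.10", "0.00", "0.10")
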