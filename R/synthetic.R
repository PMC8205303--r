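#' Configuration for the synthetic dissolved-oxygen generator
#'
#' The generator emulates the regimes a DO sensor records on a marine
#' ranch: a diurnal sinusoidal cycle, random-walk noise injected on the
#' *difference* scale (so first differences are Gaussian around the
#' cycle's slope), and mean-reverting "mutation" spikes -- a sudden jump
#' that holds for a few steps and then reverts, leaving the surrounding
#' data in stable ranges. Emitted levels are quantized to the sensor
#' resolution grid (0.01 mg/L by default), as a real instrument reports.
#'
#' Defaults describe a 5-minute sampling grid: a full diurnal cycle is
#' 288 samples, the mean level is 8 mg/L with a 1 mg/L swing, innovations
#' have 0.02 mg/L standard deviation, and spikes of 1.5 mg/L lasting 6
#' steps (30 min) occur with probability 0.002 per step.
#'
#' @param n series length (>= 2).
#' @param base mean level, mg/L.
#' @param amplitude diurnal amplitude, mg/L.
#' @param period samples per diurnal cycle.
#' @param noise_sd standard deviation of the Gaussian innovations on the
#'   difference scale, mg/L.
#' @param spike_prob per-step probability that a mutation spike starts.
#' @param spike_magnitude size of the spike jump, mg/L (sign is random).
#' @param spike_duration steps a spike holds before reverting.
#' @param quantize_decimals decimal places of the sensor resolution grid
#'   the emitted levels are rounded to; `NA` disables quantization.
#' @param seed integer RNG seed; identical config and seed give
#'   bit-identical series.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 2000L, base = 8.0, amplitude = 1.0,
                             period = 288L, noise_sd = 0.02,
                             spike_prob = 0.002, spike_magnitude = 1.5,
                             spike_duration = 6L, quantize_decimals = 2L,
                             seed = 1L) {
  cfg <- list(
    n = as.integer(n), base = base, amplitude = amplitude,
    period = as.integer(period), noise_sd = noise_sd,
    spike_prob = spike_prob, spike_magnitude = spike_magnitude,
    spike_duration = as.integer(spike_duration),
    quantize_decimals = if (is.na(quantize_decimals)) NA_integer_ else as.integer(quantize_decimals),
    seed = as.integer(seed)
  )
  if (cfg$n < 2L) stop_model_error("synthetic series length must be >= 2")
  for (f in c("amplitude", "noise_sd", "spike_prob", "spike_magnitude")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop_model_error(sprintf("synthetic config field '%s' must be >= 0", f))
    }
  }
  if (cfg$period < 1L) stop_model_error("period must be >= 1")
  if (cfg$spike_prob > 1) stop_model_error("spike_prob must be a probability")
  if (cfg$spike_duration < 1L) stop_model_error("spike_duration must be >= 1")
  structure(cfg, class = "synthetic_config")
}

#' Generate a sinusoidal DO-like level series
#'
#' Level at step t (t = 0, 1, ...) is
#' `base + amplitude * sin(2 * pi * t / period)` plus cumulated Gaussian
#' innovations (a random-walk component) plus the active spike offset,
#' rounded to the sensor resolution grid. With amplitude 0, zero noise
#' and spikes off the series is constant; with zero noise and spikes off
#' its differences form a deterministic repeating pattern of length
#' `period`.
#'
#' @param config a [synthetic_config()].
#' @return a [level_series()] on a synthetic 5-minute timestamp grid.
#' @export
generate_sinusoidal <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  withr::with_seed(config$seed, {
    t <- seq_len(n) - 1L
    cycle <- config$base + config$amplitude * sin(2 * pi * t / config$period)
    walk <- cumsum(c(0, stats::rnorm(n - 1L, 0, config$noise_sd)))
    spike <- numeric(n)
    if (config$spike_prob > 0 && config$spike_magnitude > 0) {
      starts <- stats::runif(n) < config$spike_prob
      signs <- sample(c(-1, 1), n, replace = TRUE)
      remaining <- 0L
      offset <- 0
      for (s in seq_len(n)) {
        if (remaining > 0L) {
          remaining <- remaining - 1L
        } else {
          offset <- 0
          if (starts[s]) {
            offset <- signs[s] * config$spike_magnitude
            remaining <- config$spike_duration - 1L
          }
        }
        spike[s] <- offset
      }
    }
    values <- cycle + walk + spike
    if (!is.na(config$quantize_decimals)) {
      values <- round(values, config$quantize_decimals)
    }
    level_series(values)
  })
}

#' Sample a difference-symbol sequence from a first-order Markov chain
#'
#' Ground-truth generator for accuracy-recovery checks: when the true
#' next-difference law is a known Markov chain over a small symbol set,
#' the chain's Bayes-optimal one-step accuracy is computable from the
#' transition matrix (see [markov_bayes_accuracy()]) and a learner can be
#' measured against it. The initial state is drawn from the stationary
#' distribution.
#'
#' @param transition_matrix square stochastic matrix (rows sum to 1).
#' @param symbols character vector of distinct symbols, one per state.
#' @param n sequence length.
#' @param seed integer RNG seed.
#' @return character vector of `n` symbols.
#' @export
generate_markov_diffs <- function(transition_matrix, symbols, n, seed = 1L) {
  P <- as.matrix(transition_matrix)
  k <- length(symbols)
  if (anyDuplicated(symbols)) stop_model_error("symbols must be distinct")
  if (nrow(P) != k || ncol(P) != k) {
    stop_model_error("transition matrix must be square with one row per symbol")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop_model_error("transition matrix rows must be non-negative and sum to 1")
  }
  pi0 <- markov_stationary(P)
  withr::with_seed(as.integer(seed), {
    states <- integer(n)
    states[1L] <- sample.int(k, 1L, prob = pi0)
    for (t in seq_len(n - 1L)) {
      states[t + 1L] <- sample.int(k, 1L, prob = P[states[t], ])
    }
    symbols[states]
  })
}

# Stationary distribution by eigen-decomposition of t(P).
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Bayes-optimal one-step accuracy of a Markov chain
#'
#' The best possible one-step symbol-prediction accuracy for data drawn
#' from a first-order chain: predict the modal successor of the current
#' state, so the accuracy is `sum_s pi(s) * max_t P[s, t]` under the
#' stationary distribution `pi`.
#'
#' @param transition_matrix square stochastic matrix.
#' @return accuracy in (0, 1].
#' @export
markov_bayes_accuracy <- function(transition_matrix) {
  P <- as.matrix(transition_matrix)
  pi0 <- markov_stationary(P)
  sum(pi0 * apply(P, 1, max))
}
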