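# Two-sample toy used throughout: windows (a,b -> c) and (b,c -> d).
toy_samples <- function() build_samples(c("a", "b", "c", "d"), 3)

test_that("fit enumerates pair and triple counts in one pass", {
  m <- nsb_fit(toy_samples())
  expect_equal(m$total, 2)
  expect_equal(unname(m$pair_counts[["c|1|a"]]), 1L)
  expect_equal(unname(m$triple_counts[["c|1|a|2|b"]]), 1L)
  expect_setequal(m$classes, c("c", "d"))
  expect_length(m$alphabet, 4)
})

test_that("counts are additive under sample duplication", {
  ss <- toy_samples()
  doubled <- nsb_update(nsb_fit(ss), ss)
  m <- nsb_fit(ss)
  expect_equal(doubled$total, 2 * m$total)
  expect_equal(doubled$pair_counts, 2L * m$pair_counts)
  expect_equal(doubled$triple_counts, 2L * m$triple_counts)
})

test_that("Laplace estimates match hand-evaluated values on the toy set", {
  m <- nsb_fit(toy_samples()) # total 2, N = 2 classes, A = 4 symbols
  expect_equal(laplace_joint(m, "c", 1, "a"), (1 + 1) / (2 + 2 * 4))
  expect_equal(laplace_conditional(m, "c", 1, "a", 2, "b"), (1 + 1) / (1 + 4))
  # empty-condition uniform: unseen (y, x_i) pair gives 1/A for every x_j
  expect_equal(laplace_conditional(m, "c", 1, "d", 2, "b"), 1 / 4)
  expect_error(laplace_joint(m, "c", 3, "a"), "position")
})

test_that("Laplace families normalize to one for every fitted model", {
  set.seed(23)
  for (rep in 1:20) {
    toy <- random_toy()
    m <- nsb_fit(build_samples(toy$symbols, toy$L))
    d <- m$window_length - 1L
    for (i in seq_len(d)) {
      joint_sum <- sum(outer(
        m$classes, m$alphabet,
        Vectorize(function(y, x) laplace_joint(m, y, i, x))
      ))
      expect_equal(joint_sum, 1, tolerance = 1e-12)
    }
    # conditional normalization for every (y, i, x_i) and one j
    for (y in m$classes) {
      for (i in seq_len(d)) {
        for (x_i in m$alphabet) {
          cond_sum <- sum(vapply(
            m$alphabet,
            function(x_j) laplace_conditional(m, y, i, x_i, d, x_j),
            numeric(1)
          ))
          expect_equal(cond_sum, 1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("count-table marginals are consistent", {
  set.seed(31)
  for (rep in 1:10) {
    toy <- random_toy()
    ss <- build_samples(toy$symbols, toy$L)
    m <- nsb_fit(ss)
    d <- m$window_length - 1L
    for (i in seq_len(d)) {
      keys <- grep(sprintf("^[^|]+\\|%d\\|", i), names(m$pair_counts), value = TRUE)
      expect_equal(sum(m$pair_counts[keys]), m$total)
    }
    # triple counts sum back to their pair count over x_j
    for (key in names(m$pair_counts)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      for (j in seq_len(d)) {
        tkeys <- paste(parts[1], parts[2], parts[3], j, m$alphabet, sep = "|")
        got <- m$triple_counts[tkeys]
        got[is.na(got)] <- 0L
        expect_equal(sum(got), unname(m$pair_counts[[key]]))
      }
    }
  }
})

test_that("incremental update equals refitting on the pooled samples", {
  set.seed(47)
  for (rep in 1:15) {
    toy <- random_toy()
    n_total <- length(toy$symbols) + 8L
    symbols <- sample(unique(toy$symbols), n_total, replace = TRUE)
    ss <- build_samples(symbols, toy$L)
    cut <- sample(seq_len(ss$n_samples - 1L), 1)
    d1 <- nsbforecast:::subset_samples(ss, seq_len(cut))
    d2 <- nsbforecast:::subset_samples(ss, (cut + 1L):ss$n_samples)
    upd <- nsb_update(nsb_fit(d1), d2)
    ref <- nsb_fit(nsbforecast:::combine_samples(d1, d2))
    expect_identical(upd$pair_counts, ref$pair_counts)
    expect_identical(upd$triple_counts, ref$triple_counts)
    expect_identical(upd$class_counts, ref$class_counts)
    expect_equal(upd$total, ref$total)
    expect_identical(upd$classes, ref$classes)
    expect_identical(upd$alphabet, ref$alphabet)
  }
})

test_that("update with an empty set is the identity and window lengths must match", {
  m <- nsb_fit(toy_samples())
  empty <- nsbforecast:::subset_samples(toy_samples(), integer(0))
  expect_identical(nsb_update(m, empty), m)
  expect_error(nsb_update(m, build_samples(c("a", "b"), 2)), "window length")
})

test_that("updating with a new symbol grows the alphabet and reshapes smoothing", {
  # D1: sequence a b c a with L = 2 -> samples (a->b), (b->c), (c->a)
  d1 <- build_samples(c("a", "b", "c", "a"), 2)
  m1 <- nsb_fit(d1)
  expect_length(m1$alphabet, 3)
  # P(y = b, x_1 = a) with |D| = 3, N = 3, A = 3: (1+1)/(3+9)
  expect_equal(laplace_joint(m1, "b", 1, "a"), 2 / 12)
  # D2 introduces symbol d: sample (a -> d)
  m2 <- nsb_update(m1, build_samples(c("a", "d"), 2))
  expect_length(m2$alphabet, 4)
  expect_length(m2$classes, 4)
  # same count, recomputed denominators: (1+1)/(4 + 4*4)
  expect_equal(laplace_joint(m2, "b", 1, "a"), 2 / 20)
  # conditional denominator grows from A = 3 to A = 4
  expect_equal(laplace_conditional(m1, "b", 1, "a", 1, "a"), (1 + 1) / (1 + 3))
  expect_equal(laplace_conditional(m2, "b", 1, "a", 1, "a"), (1 + 1) / (1 + 4))
})

test_that("score matches the brute-force oracle and normalizes", {
  # the 5-sample toy over the +/-0.1 alphabet
  symbols <- c("-0.10", "0.00", "0.10", "0.00", "-0.10", "0.00", "0.10")
  ss <- build_samples(symbols, 3)
  expect_equal(ss$n_samples, 5)
  m <- nsb_fit(ss)
  for (window in list(c("-0.10", "0.00"), c("0.00", "0.10"), c("0.10", "0.10"))) {
    got <- nsb_score(m, window)
    orc <- oracle_scores(ss$samples, m$alphabet, window)
    expect_lt(max(abs(got$posterior[names(orc)] - orc)), 1e-12)
    expect_equal(sum(got$posterior), 1, tolerance = 1e-12)
    expect_equal(exp(got$log_score) / sum(exp(got$log_score)),
      got$posterior,
      tolerance = 1e-12
    )
  }
  expect_error(nsb_score(m, c("0.00", "0.00", "0.00")), "window")
})

test_that("a dominant class wins and tie-breaks are deterministic", {
  rep_ss <- build_samples(rep(c("a", "b", "c"), 10), 3)
  m <- nsb_fit(rep_ss)
  expect_equal(predict_next(m, c("a", "b")), "c")

  # symmetric counts, equal class frequency: |-0.1| = |0.1| so the
  # smaller signed value wins
  sym <- build_samples(c("0.00", "-0.10", "0.00", "0.10"), 2)
  msym <- nsb_fit(sym)
  sc <- nsb_score(msym, "0.00")$posterior
  expect_equal(sc[["-0.10"]], sc[["0.10"]])
  expect_equal(predict_next(msym, "0.00"), "-0.10")

  # all-unseen window makes every class score equal; the larger training
  # frequency breaks the tie
  skew <- build_samples(c("0.10", "0.00", "0.10", "0.10", "0.10"), 2)
  mskew <- nsb_fit(skew) # labels: 0.00 x1, 0.10 x3
  sc2 <- nsb_score(mskew, "0.20")$posterior
  expect_equal(sc2[["0.00"]], sc2[["0.10"]])
  expect_equal(predict_next(mskew, "0.20"), "0.10")
})

test_that("a deterministic repeating pattern is predicted exactly", {
  # period-3 diff pattern (0.1, 0.1, -0.2); with L = 4 each window of 3
  # previous diffs determines the next
  pattern <- rep(c("0.10", "0.10", "-0.20"), 30)
  ss <- build_samples(pattern, 4)
  m <- nsb_fit(ss)
  windows <- list(
    c("0.10", "0.10", "-0.20"),
    c("0.10", "-0.20", "0.10"),
    c("-0.20", "0.10", "0.10")
  )
  nexts <- c("0.10", "0.10", "-0.20")
  for (k in seq_along(windows)) {
    expect_equal(predict_next(m, windows[[k]]), nexts[k])
  }
})

test_that("walk-forward forecasting aligns to observed history", {
  # persistence-equivalent model: trained on a constant series it only
  # ever predicts a zero difference
  const <- level_series(rep(8, 50))
  m <- suppressMessages(nsb_train(const, 3, gamma = 0))
  test <- level_series(8 + cumsum(c(0, round(rnorm(19, 0, 0.05), 2))))
  fc <- forecast_series(m, test)
  expect_equal(nrow(fc), 19 - (3 - 1)) # diff count minus (L - 1)
  expect_equal(fc$predicted_diff, rep(0, nrow(fc)))
  # forecast equals the lagged observations
  expect_equal(fc$predicted_level, test$value[3:19])
  expect_equal(fc$observed, test$value[4:20])
  expect_error(forecast_series(m, level_series(c(8, 8.1, 8.2))), "at least")
})

test_that("models survive a JSON round trip with identical predictions", {
  set.seed(91)
  syms <- discretize(rnorm(120, 0, 0.04), 2)
  m <- nsb_fit(filter_by_frequency(build_samples(syms, 3), 0.02), gamma = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  nsb_save(m, path)
  back <- nsb_load(path)
  expect_identical(back$pair_counts, m$pair_counts)
  expect_identical(back$triple_counts, m$triple_counts)
  expect_identical(back$alphabet, m$alphabet)
  expect_equal(back$gamma, m$gamma)
  probe <- replicate(10, sample(m$alphabet, 2), simplify = FALSE)
  for (w in probe) {
    expect_identical(predict_next(back, w), predict_next(m, w))
    expect_equal(nsb_score(back, w)$posterior, nsb_score(m, w)$posterior)
  }
  expect_error(nsb_load("/nonexistent/model.json"), class = "nsb_io_error")
})
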