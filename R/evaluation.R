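#' Forecast error metrics
#'
#' Standard pointwise error functions between an observed and a predicted
#' series: mean absolute error, root mean square error, and mean absolute
#' percentage error (reported as a proportion, not multiplied by 100).
#'
#' @param observed,predicted numeric vectors of equal length (>= 1).
#' @return a single numeric value.
#' @export
mae <- function(observed, predicted) {
  check_pair(observed, predicted)
  mean(abs(predicted - observed))
}

#' @rdname mae
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname mae
#' @export
mape <- function(observed, predicted) {
  check_pair(observed, predicted)
  if (any(observed == 0)) {
    stop_model_error("MAPE is undefined when an observed value is zero")
  }
  mean(abs((predicted - observed) / observed))
}

check_pair <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
    length(observed) != length(predicted) || length(observed) < 1L) {
    stop_model_error("observed and predicted must be numeric vectors of equal length >= 1")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop_model_error("metrics inputs contain missing values")
  }
  invisible(TRUE)
}

#' Willmott's index of agreement
#'
#' A standardized agreement measure in \[0, 1\]:
#' \deqn{WIA = 1 - \frac{\sum_i (O_i - P_i)^2}
#'   {\sum_i (|P_i - \bar O| + |O_i - \bar O|)^2}}
#' with \eqn{\bar O} the mean observation. 1 means the predictions match
#' the observations perfectly; 0 means no agreement at all. Models with
#' WIA above 0.6 are conventionally considered to have predictive value.
#' When predicted and observed are identical (including both constant)
#' the index is 1 by the perfect-match anchor.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return a value in \[0, 1\].
#' @export
wia <- function(observed, predicted) {
  check_pair(observed, predicted)
  if (length(observed) < 2L) {
    stop_model_error("WIA needs at least 2 points")
  }
  if (all(observed == predicted)) {
    return(1)
  }
  obar <- mean(observed)
  num <- sum((observed - predicted)^2)
  den <- sum((abs(predicted - obar) + abs(observed - obar))^2)
  1 - num / den
}

#' Bundle the four evaluation metrics
#'
#' @inheritParams wia
#' @return list of class `metrics_report` with fields `mae`, `rmse`,
#'   `mape`, `wia` and `n`.
#' @export
metrics_report <- function(observed, predicted) {
  structure(
    list(
      mae = mae(observed, predicted),
      rmse = rmse(observed, predicted),
      mape = mape(observed, predicted),
      wia = wia(observed, predicted),
      n = length(observed)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d\n  MAE  %.6f mg/L\n  RMSE %.6f mg/L\n  MAPE %.6f (%.4f%%)\n  WIA  %.6f\n",
    x$n, x$mae, x$rmse, x$mape, 100 * x$mape, x$wia
  ))
  invisible(x)
}

#' Diebold-Mariano forecast-comparison test
#'
#' Tests whether two competing forecasts of the same series differ in
#' expected loss. For one-step-ahead forecasts the loss differential
#' \eqn{d_t = g(e_{a,t}) - g(e_{b,t})} is taken serially uncorrelated
#' (truncation lag 0), so the statistic is
#' \eqn{\bar d / \sqrt{s_d^2 / n}} with \eqn{s_d^2} the sample variance
#' of \eqn{d_t}, referred to the standard normal (two-sided). The larger
#' the absolute statistic, the more significantly the two forecasts
#' differ. Combined with the absolute-error loss this is the DM-MAE
#' variant; with absolute percentage error, DM-MAPE.
#'
#' @param errors_a,errors_b forecast-error series (predicted minus
#'   observed) of the two models, equal length `n >= 10`.
#' @param loss `"absolute"` (DM-MAE) or `"absolute_percentage"`
#'   (DM-MAPE; requires `observed`).
#' @param observed observed series, needed only for percentage loss.
#' @param harvey apply the Harvey-Leybourne-Newbold small-sample
#'   correction and a t reference with `n - 1` degrees of freedom
#'   (default `FALSE`: classic large-sample normal test).
#' @return list of class `dm_result` with `statistic`, `p_value`, `loss`
#'   and `n`. A degenerate zero-variance differential gives statistic 0
#'   and p 1 when the mean differential is also zero, otherwise
#'   `+/-Inf` with p 0.
#' @export
dm_test <- function(errors_a, errors_b,
                    loss = c("absolute", "absolute_percentage"),
                    observed = NULL, harvey = FALSE) {
  loss <- match.arg(loss)
  if (length(errors_a) != length(errors_b)) {
    stop_model_error("error series must have equal length")
  }
  n <- length(errors_a)
  if (n < 10L) {
    stop_model_error("the DM test needs at least 10 forecast errors")
  }
  g <- switch(loss,
    absolute = function(e, o) abs(e),
    absolute_percentage = function(e, o) {
      if (is.null(o)) {
        stop_model_error("percentage loss needs the observed series")
      }
      if (length(o) != length(e)) {
        stop_model_error("observed series length must match the errors")
      }
      if (any(o == 0)) {
        stop_model_error("percentage loss is undefined when an observed value is zero")
      }
      abs(e / o)
    }
  )
  d <- g(errors_a, observed) - g(errors_b, observed)
  dbar <- mean(d)
  s2 <- stats::var(d)
  if (s2 == 0) {
    if (dbar == 0) {
      stat <- 0
      p <- 1
    } else {
      stat <- sign(dbar) * Inf
      p <- 0
    }
  } else {
    stat <- dbar / sqrt(s2 / n)
    if (harvey) {
      # horizon h = 1: correction factor sqrt((n + 1 - 2h + h(h-1)/n) / n)
      stat <- stat * sqrt((n - 1) / n)
      p <- 2 * stats::pt(-abs(stat), df = n - 1)
    } else {
      p <- 2 * stats::pnorm(-abs(stat))
    }
  }
  structure(
    list(statistic = stat, p_value = p, loss = loss, n = n),
    class = "dm_result"
  )
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf(
    "<dm_result> loss = %s, n = %d\n  statistic %.6f, p-value %.6g\n",
    x$loss, x$n, x$statistic, x$p_value
  ))
  invisible(x)
}
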