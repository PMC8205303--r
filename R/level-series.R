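#' Construct a level series
#'
#' A level series is an ordered set of continuous measurements (dissolved
#' oxygen in mg/L, or any other water-quality parameter) at uniformly
#' spaced time points. Timestamps are carried for labelling output but are
#' never used in computation; irregular spacing triggers a warning, not an
#' error. Missing values are rejected rather than imputed: the forecaster
#' works on the raw series and must not silently modify the data.
#'
#' @param values numeric vector of measurements (mg/L). No `NA`/`NaN`.
#' @param timestamps optional `POSIXct` vector, strictly increasing, same
#'   length as `values`. Defaults to a synthetic 5-minute grid starting at
#'   2021-01-01 00:00 UTC.
#' @return A data frame of class `level_series` with columns `timestamp`
#'   and `value`.
#' @export
#' @examples
#' s <- level_series(c(8.0, 8.1, 8.05))
#' first_difference(s)
level_series <- function(values, timestamps = NULL) {
  if (!is.numeric(values) || length(values) < 1L) {
    stop_model_error("a level series needs at least one numeric value")
  }
  if (anyNA(values)) {
    stop_model_error("level series contains missing (NA/NaN) values; remove or re-export them -- the model does not impute")
  }
  values <- as.numeric(values)
  if (is.null(timestamps)) {
    timestamps <- seq(
      from = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
      by = 300, length.out = length(values)
    )
  }
  if (length(timestamps) != length(values)) {
    stop_model_error("timestamps and values must have equal length")
  }
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (anyNA(timestamps)) {
    stop_model_error("unparseable timestamps in level series")
  }
  dt <- diff(as.numeric(timestamps))
  if (length(dt) > 0L && any(dt <= 0)) {
    stop_model_error("timestamps must be strictly increasing")
  }
  if (length(dt) > 1L && diff(range(dt)) > 1e-6 * max(dt)) {
    warning("level series is not uniformly sampled; computations assume uniform spacing",
      call. = FALSE
    )
  }
  structure(
    data.frame(timestamp = timestamps, value = values),
    class = c("level_series", "data.frame")
  )
}

as_level_series <- function(x) {
  if (inherits(x, "level_series")) return(x)
  if (is.numeric(x)) return(level_series(x))
  stop_model_error("cannot interpret input as a level series")
}

#' @export
print.level_series <- function(x, ...) {
  cat(sprintf(
    "<level_series> %d points, %s .. %s, value range [%.3f, %.3f]\n",
    nrow(x), format(x$timestamp[1L]), format(x$timestamp[nrow(x)]),
    min(x$value), max(x$value)
  ))
  invisible(x)
}

#' Read and write level-series CSV files
#'
#' The on-disk format is a two-column CSV with header `timestamp,value`;
#' timestamps are ISO-8601 strings or epoch seconds, values use a decimal
#' point with no thousands separators.
#'
#' @param path file path.
#' @return `read_level_csv()` returns a [level_series()].
#' @export
read_level_csv <- function(path) {
  if (!file.exists(path)) {
    stop_io_error(sprintf("input file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_io_error(sprintf("failed to read %s: %s", path, conditionMessage(e)))
  )
  if (!all(c("timestamp", "value") %in% names(df))) {
    stop_io_error(sprintf("%s must have columns 'timestamp' and 'value'", path))
  }
  ts_raw <- df$timestamp
  ts <- if (is.numeric(ts_raw)) {
    as.POSIXct(ts_raw, origin = "1970-01-01", tz = "UTC")
  } else {
    parsed <- as.POSIXct(ts_raw, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
    ))
    parsed
  }
  level_series(as.numeric(df$value), ts)
}

#' @param series a [level_series()].
#' @rdname read_level_csv
#' @export
write_level_csv <- function(series, path) {
  series <- as_level_series(series)
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = series$value
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chronological train/test split
#'
#' Splits a level series into a training head and a test tail with no
#' shuffling: the training set gets the first `floor(fraction * m)` points
#' and the test set the remainder, so concatenating the two outputs
#' reproduces the input.
#'
#' @param series a [level_series()].
#' @param fraction proportion of points assigned to the training set,
#'   strictly between 0 and 1 (default 0.9).
#' @return list with elements `train` and `test`, both `level_series`.
#' @export
split_train_test <- function(series, fraction = 0.9) {
  series <- as_level_series(series)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1) {
    stop_model_error("split fraction must lie strictly between 0 and 1")
  }
  m <- nrow(series)
  n_train <- floor(fraction * m)
  if (n_train < 2L || m - n_train < 2L) {
    stop_model_error(sprintf(
      "split of %d points at fraction %g leaves fewer than 2 points on one side",
      m, fraction
    ))
  }
  idx <- seq_len(n_train)
  list(
    train = level_series(series$value[idx], series$timestamp[idx]),
    test = level_series(series$value[-idx], series$timestamp[-idx])
  )
}
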