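#' Binary sensor series on the 15-minute grid
#'
#' A `bar_series` holds the 0/1 activity of one sensor on a regular
#' 15-minute grid anchored at local midnight: value `t` is 1 when the sensor
#' fired at least once in the half-open interval
#' `[grid_start + (t-1) * 15min, grid_start + t * 15min)`.
#'
#' @param values integer or numeric vector of 0/1 indicators, length >= 1.
#' @param sensor_id non-empty sensor label.
#' @param grid_start `POSIXct` anchor of bin 1; must be midnight-aligned.
#' @param bins_per_day bins per day; 96 corresponds to the 15-minute grid
#'   and is the only supported value.
#' @return an object of class `bar_series`.
#' @export
bar_series <- function(values, sensor_id,
                       grid_start = as.POSIXct("2020-01-01", tz = "UTC"),
                       bins_per_day = 96L) {
  stopifnot(is.character(sensor_id), length(sensor_id) == 1, nzchar(sensor_id))
  values <- as.integer(values)
  if (length(values) < 1 || anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("`values` must be a non-empty vector of 0/1 indicators")
  if (bins_per_day != 96L)
    stop("only bins_per_day = 96 (15-minute bins) is supported")
  grid_start <- as.POSIXct(grid_start, tz = "UTC")
  if (length(grid_start) != 1 || is.na(grid_start))
    stop("`grid_start` must be a single valid datetime")
  midnight <- as.numeric(grid_start) %% 86400
  if (midnight != 0)
    stop("`grid_start` must be aligned to midnight")
  structure(
    list(sensor_id = sensor_id, values = values,
         grid_start = grid_start, bins_per_day = as.integer(bins_per_day)),
    class = "bar_series"
  )
}

#' @export
length.bar_series <- function(x) length(x$values)

#' @export
print.bar_series <- function(x, ...) {
  cat(sprintf("<bar_series> sensor '%s': %d bins (%.1f days) from %s, %d active\n",
              x$sensor_id, length(x$values), length(x$values) / x$bins_per_day,
              format(x$grid_start, "%Y-%m-%d %H:%M", tz = "UTC"),
              sum(x$values)))
  invisible(x)
}

#' Read a sensor event log from CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `sensor_id`. Records need not
#' be sorted; unparseable timestamps are rejected with the offending record
#' index.
#'
#' @param path CSV file path.
#' @return data.frame with `timestamp` (POSIXct) and `sensor_id` columns.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "sensor_id") %in% names(df)))
    stop("event log must have columns `timestamp` and `sensor_id`")
  parse_event_log(df)
}

# validate/parse an in-memory event log data.frame
parse_event_log <- function(df) {
  raw <- as.character(df$timestamp)
  ts <- .POSIXct(rep(NA_real_, length(raw)), tz = "UTC")
  # per-record fallback through the accepted formats, most specific first
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(raw[need], tz = "UTC", format = fmt, optional = TRUE)
  }
  bad <- which(is.na(ts) & !is.na(raw))
  if (length(bad))
    stop(sprintf("unparseable timestamp at record(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  if (anyNA(ts)) stop("missing timestamps in event log")
  id <- as.character(df$sensor_id)
  if (any(!nzchar(id) | is.na(id))) stop("empty sensor_id in event log")
  data.frame(timestamp = ts, sensor_id = id, stringsAsFactors = FALSE)
}

#' Binarize raw sensor events onto the 15-minute grid
#'
#' Bin `t` is 1 iff at least one event of `sensor_id` falls inside the
#' half-open 15-minute interval ending at grid time `t`; multiple events in
#' one bin collapse to a single 1, and events exactly on a bin boundary
#' belong to the later bin.  Events outside `[start, end)` are ignored.
#'
#' @param events event log data.frame (`timestamp`, `sensor_id`), e.g. from
#'   [read_event_log()].
#' @param sensor_id sensor to extract; if absent from the log the result is
#'   an all-zero series with a warning.
#' @param start midnight-aligned POSIXct start of the grid.
#' @param end POSIXct end of the grid (exclusive), a whole number of bins
#'   after `start`.
#' @return [bar_series] of length `(end - start) / 15min`.
#' @export
binarize_events <- function(events, sensor_id, start, end) {
  events <- parse_event_log(events)
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(end > start)) stop("`end` must be after `start`")
  span <- as.numeric(end) - as.numeric(start)
  if (span %% SECONDS_PER_BIN != 0)
    stop("`end - start` must be a whole number of 15-minute bins")
  n_bins <- as.integer(span %/% SECONDS_PER_BIN)
  values <- integer(n_bins)
  sel <- events$sensor_id == sensor_id
  if (!any(sel)) {
    warning(sprintf("sensor '%s' absent from event log: all-zero series", sensor_id))
  } else {
    offset <- as.numeric(events$timestamp[sel]) - as.numeric(start)
    idx <- floor(offset / SECONDS_PER_BIN) + 1
    idx <- idx[idx >= 1 & idx <= n_bins]
    values[unique(idx)] <- 1L
  }
  bar_series(values, sensor_id, grid_start = start)
}

#' Reconstruct an event log from a binary series
#'
#' Emits one event per active bin, stamped at the bin's start time.
#' Binarizing the result over the same window returns the identical series.
#'
#' @param series a [bar_series].
#' @return event-log data.frame (`timestamp`, `sensor_id`).
#' @export
events_from_series <- function(series) {
  stopifnot(inherits(series, "bar_series"))
  on_bins <- which(series$values == 1L)
  data.frame(
    timestamp = series$grid_start + (on_bins - 1) * SECONDS_PER_BIN,
    sensor_id = rep(series$sensor_id, length(on_bins)),
    stringsAsFactors = FALSE
  )
}

#' Write binarized series to CSV
#'
#' Columns `datetime,sensor_id,value`, one row per bin (datetime is the bin
#' start).  Several series may be written together; [read_binary_series()]
#' inverts the format.
#'
#' @param series a [bar_series] or list of them.
#' @param path output CSV path.
#' @export
write_binary_series <- function(series, path) {
  if (inherits(series, "bar_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      datetime = format(s$grid_start + (seq_along(s$values) - 1) * SECONDS_PER_BIN,
                        "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      sensor_id = s$sensor_id,
      value = s$values,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binarized series from CSV
#'
#' @param path CSV written by [write_binary_series()].
#' @return named list of [bar_series], one per sensor present.
#' @export
read_binary_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("datetime", "sensor_id", "value") %in% names(df)))
    stop("binary series CSV must have columns datetime, sensor_id, value")
  out <- lapply(split(df, df$sensor_id), function(d) {
    ts <- as.POSIXct(d$datetime, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    d <- d[order(ts), ]
    bar_series(d$value, d$sensor_id[1], grid_start = min(ts))
  })
  out[order(names(out))]
}

#' Assemble aligned household series
#'
#' Splits a collection of binarized sensor series into the modelled target
#' `y` and its `J` covariate sensors `z_j` (label-sorted for a deterministic
#' order).  All series must share length and grid anchor.
#'
#' @param series list of [bar_series] (the target among them).
#' @param target_id label of the sensor to model.
#' @return object of class `bar_household` with elements `target`,
#'   `covariates` (named list, possibly empty), and `T`.
#' @export
assemble_household <- function(series, target_id) {
  if (inherits(series, "bar_series")) series <- list(series)
  stopifnot(length(series) >= 1, all(vapply(series, inherits, TRUE, "bar_series")))
  ids <- vapply(series, function(s) s$sensor_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sensor labels: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!target_id %in% ids)
    stop(sprintf("target sensor '%s' not among: %s", target_id,
                 paste(ids, collapse = ", ")))
  T_len <- length(series[[1]]$values)
  anchor <- series[[1]]$grid_start
  for (s in series) {
    if (length(s$values) != T_len || s$grid_start != anchor)
      stop(sprintf("series '%s' is not aligned with '%s' (length or grid_start differ)",
                   s$sensor_id, series[[1]]$sensor_id))
  }
  names(series) <- ids
  covs <- series[setdiff(sort(ids), target_id)]
  structure(
    list(target = series[[target_id]], covariates = covs, T = T_len),
    class = "bar_household"
  )
}

#' @export
print.bar_household <- function(x, ...) {
  cat(sprintf("<bar_household> target '%s', %d covariates, T = %d bins (%.1f days)\n",
              x$target$sensor_id, length(x$covariates), x$T,
              x$T / x$target$bins_per_day))
  if (length(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

# covariate matrix (T x J) of a household; J = 0 gives a 0-column matrix
covariate_matrix <- function(hh) {
  J <- length(hh$covariates)
  if (J == 0) return(matrix(0, nrow = hh$T, ncol = 0))
  vapply(hh$covariates, function(s) as.numeric(s$values), numeric(hh$T))
}

# slice a household to a contiguous bin range (used for train/test splits);
# `from` must keep the grid midnight-anchored, i.e. from - 1 divisible by 96
slice_household <- function(hh, from, to) {
  stopifnot(from >= 1, to <= hh$T, from <= to, (from - 1) %% 96 == 0)
  cut1 <- function(s) {
    bar_series(s$values[from:to], s$sensor_id,
               grid_start = s$grid_start + (from - 1) * SECONDS_PER_BIN)
  }
  assemble_household(c(list(cut1(hh$target)), lapply(hh$covariates, cut1)),
                     target_id = hh$target$sensor_id)
}

# concatenate two aligned households (train history followed by test window)
concat_household <- function(train, test) {
  stopifnot(inherits(train, "bar_household"), inherits(test, "bar_household"))
  if (!identical(sort(names(train$covariates)), sort(names(test$covariates))) ||
      train$target$sensor_id != test$target$sensor_id)
    stop("train and test households must carry the same sensors")
  glue <- function(a, b) bar_series(c(a$values, b$values), a$sensor_id,
                                    grid_start = a$grid_start)
  assemble_household(
    c(list(glue(train$target, test$target)),
      lapply(names(train$covariates),
             function(nm) glue(train$covariates[[nm]], test$covariates[[nm]]))),
    target_id = train$target$sensor_id
  )
}
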