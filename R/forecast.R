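#' One-step-ahead trigger probability
#'
#' `P(Y_{t+1} = 1 | history through t)` under fitted parameters: the
#' component recursions are run over the full observed history and the
#' probability for the next bin is read off.  Identical to the `p` that
#' [compute_trace()] would assign at position `T + 1` of the extended
#' series (the predictor at `t + 1` depends only on data up to `t`).
#'
#' @param params a [bar_params].
#' @param history a [bar_household] holding everything observed so far.
#' @return scalar probability for bin `T + 1`.
#' @export
one_step_forecast <- function(params, history) {
  stopifnot(inherits(history, "bar_household"))
  pad1 <- function(s) bar_series(c(s$values, 0L), s$sensor_id,
                                 grid_start = s$grid_start)
  ext <- assemble_household(
    c(list(pad1(history$target)), lapply(history$covariates, pad1)),
    target_id = history$target$sensor_id
  )
  tr <- compute_trace(params, ext)
  unname(tr$p[ext$T])
}

#' One-step-ahead forecasts over a held-out window
#'
#' Simulates the online process: for every bin of `test` the probability is
#' computed from the realized history (train plus test bins already seen),
#' which for this model is exactly the trace of the concatenated series
#' restricted to the test window.  The first `burn_in` forecasts (one day)
#' are flagged for discarding because the seasonal component has no full
#' previous day inside the window.
#'
#' @param params a [bar_params].
#' @param train [bar_household] used as history (typically the fitting
#'   window).
#' @param test [bar_household] holding the held-out window, contiguous with
#'   `train` and carrying the same sensors.
#' @param burn_in number of leading forecasts to discard downstream.
#' @return object of class `bar_forecast`: `p_hat` (aligned to the test
#'   grid), `burn_in`, `bins_per_day`, `grid_start`.
#' @export
forecast_path <- function(params, train, test, burn_in = 96L) {
  full <- concat_household(train, test)
  tr <- compute_trace(params, full)
  p_hat <- tr$p[(train$T + 1):full$T]
  new_forecast(p_hat, burn_in, test)
}

new_forecast <- function(p_hat, burn_in, test) {
  structure(
    list(p_hat = as.numeric(p_hat), burn_in = as.integer(burn_in),
         bins_per_day = test$target$bins_per_day,
         grid_start = test$target$grid_start),
    class = "bar_forecast"
  )
}

#' @export
print.bar_forecast <- function(x, ...) {
  cat(sprintf("<bar_forecast> %d one-step-ahead probabilities (%.1f days), burn-in %d bins\n",
              length(x$p_hat), length(x$p_hat) / x$bins_per_day, x$burn_in))
  invisible(x)
}

#' Stack forecast probabilities by time-of-day bin
#'
#' After dropping the burn-in day, groups the forecast probabilities by
#' their 15-minute time-of-day bin `w = 1..96`; a 28-day window yields 27
#' probabilities per bin.  The stacks feed the Poisson-binomial band.
#'
#' @param forecast a [bar_forecast] (the test grid must start at midnight).
#' @return list of 96 numeric vectors (possibly of unequal length when the
#'   horizon is not a whole number of days).
#' @export
stack_by_bin <- function(forecast) {
  stopifnot(inherits(forecast, "bar_forecast"))
  n <- length(forecast$p_hat)
  bpd <- forecast$bins_per_day
  if (n < 2 * bpd)
    stop("forecast horizon must be at least 2 days (burn-in day plus one)")
  keep <- (forecast$burn_in + 1):n
  w <- ((keep - 1) %% bpd) + 1
  split(forecast$p_hat[keep], factor(w, levels = 1:bpd))
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of a sum of independent but not identically distributed
#' Bernoulli trials, computed by iterative convolution (O(n^2), exact).
#' Mean `sum(p_i)` and variance `sum(p_i (1 - p_i))`.
#'
#' @param probs success probabilities in `[0, 1]`.
#' @return numeric vector of length `length(probs) + 1`: `P(X = k)` for
#'   `k = 0..n`.
#' @export
poisson_binomial_pmf <- function(probs) {
  probs <- as.numeric(probs)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

# integer quantile of a pmf over 0..n: smallest k with CDF(k) >= q
pmf_quantile <- function(pmf, q) {
  cdf <- cumsum(pmf)
  # tolerance absorbs convolution round-off at exact-quantile boundaries
  which(cdf >= q - 1e-12)[1] - 1L
}

#' Per-bin 95% Poisson-binomial quantile band
#'
#' For every time-of-day bin, the stacked daily forecast probabilities
#' define a Poisson-binomial count distribution; the band is its
#' `[q_lo, q_hi]` integer quantile interval (defaults 2.5% and 97.5%).
#'
#' @param stacks list of per-bin probability vectors from [stack_by_bin()],
#'   or a [bar_forecast] (stacked internally).
#' @param q_lo,q_hi band quantiles.
#' @return object of class `bar_band`: data.frame `bin`, `lower`, `upper`,
#'   `n` plus the stacked probabilities as attribute `"stacks"`.
#' @export
quantile_band <- function(stacks, q_lo = 0.025, q_hi = 0.975) {
  if (inherits(stacks, "bar_forecast")) stacks <- stack_by_bin(stacks)
  stopifnot(is.list(stacks), length(stacks) >= 1, q_lo < q_hi)
  if (any(vapply(stacks, length, integer(1)) == 0))
    stop("every bin needs at least one probability")
  qs <- vapply(stacks, function(p) {
    pmf <- poisson_binomial_pmf(p)
    c(pmf_quantile(pmf, q_lo), pmf_quantile(pmf, q_hi))
  }, numeric(2))
  band <- data.frame(bin = seq_along(stacks),
                     lower = as.integer(qs[1, ]),
                     upper = as.integer(qs[2, ]),
                     n = vapply(stacks, length, integer(1)),
                     row.names = NULL)
  attr(band, "stacks") <- stacks
  class(band) <- c("bar_band", "data.frame")
  band
}

#' Validate a quantile band against held-out counts
#'
#' Sums the observed target activity per time-of-day bin over the held-out
#' window (burn-in day excluded, mirroring the forecast stacks) and flags
#' the bins whose empirical count escapes the closed interval
#' `[lower, upper]`.  The count of such bins — out of 96 — is the model's
#' validation statistic: about 5% of bins at most are expected outside a
#' well-calibrated 95% band.
#'
#' @param y_test [bar_series] of the target over the held-out window (same
#'   grid the forecasts were made on).
#' @param band a [bar_band].
#' @param burn_in leading bins to exclude from counting (one day).
#' @return object of class `bar_validation`: `counts` (96 integers),
#'   `n_outside`, `outside_bins`, and the band.
#' @export
validate_band <- function(y_test, band, burn_in = 96L) {
  stopifnot(inherits(y_test, "bar_series"), inherits(band, "bar_band"))
  n <- length(y_test$values)
  bpd <- y_test$bins_per_day
  if (nrow(band) != bpd)
    stop("band does not cover the day grid of the test series")
  if (n <= burn_in) stop("test window shorter than the burn-in day")
  keep <- (burn_in + 1):n
  w <- factor(((keep - 1) %% bpd) + 1, levels = 1:bpd)
  counts <- as.integer(tapply(y_test$values[keep], w, sum, default = 0L))
  outside <- counts < band$lower | counts > band$upper
  structure(
    list(counts = counts, n_outside = sum(outside),
         outside_bins = which(outside), band = band),
    class = "bar_validation"
  )
}

#' @export
print.bar_validation <- function(x, ...) {
  cat(sprintf("<bar_validation> %d of %d bins outside the quantile band\n",
              x$n_outside, length(x$counts)))
  if (x$n_outside)
    cat("  outside bins:", paste(x$outside_bins, collapse = ", "), "\n")
  invisible(x)
}

#' Plot observed counts against the quantile band
#'
#' Base-graphics rendering of the per-bin event counts over the held-out
#' window with the 95% Poisson-binomial band shaded behind them.
#'
#' @param x a [bar_validation].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bar_validation <- function(x, main = "Events per 15-minute bin vs 95% quantile band", ...) {
  b <- x$band
  graphics::plot(b$bin, x$counts, type = "n",
                 xlab = "15-minute bin of the day", ylab = "events over window",
                 ylim = range(0, x$counts, b$upper), main = main, ...)
  graphics::polygon(c(b$bin, rev(b$bin)), c(b$lower, rev(b$upper)),
                    col = "grey85", border = NA)
  graphics::lines(b$bin, x$counts, lwd = 1.5)
  if (x$n_outside)
    graphics::points(x$outside_bins, x$counts[x$outside_bins],
                     pch = 19, col = "red3")
  invisible(x)
}

#' Write band and validation report as CSV
#'
#' Columns `bin,lower,upper,count,outside`.
#'
#' @param validation a [bar_validation].
#' @param path output CSV path.
#' @export
write_validation <- function(validation, path) {
  stopifnot(inherits(validation, "bar_validation"))
  b <- validation$band
  utils::write.csv(
    data.frame(bin = b$bin, lower = b$lower, upper = b$upper,
               count = validation$counts,
               outside = as.integer(seq_len(nrow(b)) %in% validation$outside_bins)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
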