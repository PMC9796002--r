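#' Two-peak daily activity profile
#'
#' Default 96-bin day profile for simulated covariate sensors: a sharp
#' morning peak (06:00-09:00), a smaller evening peak (21:00-23:00) and a
#' low daytime baseline — the qualitative shape of bedroom/kettle activity
#' in a single-occupant household.  Used as a stand-in wherever a real
#' observed covariate stream is unavailable.
#'
#' @param baseline,morning,evening per-bin trigger probabilities.
#' @return numeric vector of 96 probabilities.
#' @export
day_profile_two_peak <- function(baseline = 0.02, morning = 0.35, evening = 0.25) {
  prof <- rep(baseline, 96)
  prof[25:36] <- morning   # 06:00-09:00
  prof[85:92] <- evening   # 21:00-23:00
  prof
}

#' Simulate a covariate sensor stream from a daily profile
#'
#' Independent Bernoulli draws per bin, with the bin's probability taken
#' from the 96-bin day profile (repeated across days).
#'
#' @param profile numeric vector of 96 per-bin probabilities.
#' @param n_days number of days to simulate.
#' @param sensor_id label for the resulting series.
#' @param grid_start grid anchor (midnight-aligned).
#' @param seed optional RNG seed (global RNG state is restored afterwards).
#' @return a [bar_series] of length `96 * n_days`.
#' @export
simulate_covariate <- function(profile, n_days, sensor_id = "z",
                               grid_start = as.POSIXct("2020-01-01", tz = "UTC"),
                               seed = NULL) {
  stopifnot(length(profile) == 96, all(profile >= 0 & profile <= 1), n_days >= 1)
  p <- rep(profile, n_days)
  vals <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  bar_series(vals, sensor_id, grid_start = grid_start)
}

#' Simulate a target sensor from the Bernoulli autoregressive model
#'
#' Sequential generation: at each bin the linear predictor is built from
#' the realized history with the same recursions as [compute_trace()], and
#' `y_t ~ Bernoulli(p_t)` is drawn.  Covariate streams are supplied (not
#' co-generated); the trace computed on the output reproduces the
#' generating probabilities exactly.
#'
#' @param params a [bar_params]; sensors named in it must appear in
#'   `covariates`.
#' @param n_days days to simulate.
#' @param covariates named list of [bar_series] (may be empty).
#' @param target_id label of the simulated sensor.
#' @param seed optional RNG seed.
#' @return a [bar_household] with the simulated target and the given
#'   covariates.
#' @export
simulate_bar <- function(params, n_days, covariates = list(),
                         target_id = "X", seed = NULL) {
  stopifnot(inherits(params, "bar_params"), n_days >= 1)
  T_len <- 96L * as.integer(n_days)
  covariates <- check_sim_covariates(covariates, T_len, params)
  grid_start <- if (length(covariates)) covariates[[1]]$grid_start
                else as.POSIXct("2020-01-01", tz = "UTC")
  Z <- if (length(covariates))
    vapply(covariates, function(s) as.numeric(s$values), numeric(T_len))
  sens_idx <- match(names(params$sensors), names(covariates))

  y <- integer(T_len)
  with_seed(seed, {
    u <- stats::runif(T_len)
    b <- 0
    cc <- numeric(length(params$sensors))
    d_buf <- numeric(96)  # d_{t-96..t-1}, ring buffer
    for (t in seq_len(T_len)) {
      if (t > 1) {
        if (!is.null(params$ar))
          b <- params$ar[2] * b + params$ar[1] * y[t - 1]
        for (j in seq_along(sens_idx))
          cc[j] <- params$sensors[[j]][2] * cc[j] +
                   params$sensors[[j]][1] * Z[t - 1, sens_idx[j]]
      }
      slot <- ((t - 1) %% 96) + 1
      d <- 0
      if (!is.null(params$seasonal) && t >= 97) {
        m <- max(y[max(1, t - 97):(t - 95)])
        d <- params$seasonal[2] * d_buf[slot] + params$seasonal[1] * m
      }
      d_buf[slot] <- d
      p_t <- inv_logit(params$a + b + sum(cc) + d)
      y[t] <- as.integer(u[t] < p_t)
    }
  })
  assemble_household(
    c(list(bar_series(y, target_id, grid_start = grid_start)), covariates),
    target_id = target_id
  )
}

#' Simulate a target sensor from the logistic baseline model
#'
#' Sequential generation with the lag-1 predictor `a + pi_b * y_{t-1} +
#' sum_j tau_j * z_{j,t-1} + pi_d * seasonal`; before bin 97 the seasonal
#' contribution is zero (no full previous day), and `y_0 = 0`.
#'
#' @param coef named coefficients as produced by [fit_logistic()]: `a`,
#'   `pi_b`, one `tau_<sensor>` per covariate, `pi_d`.
#' @inheritParams simulate_bar
#' @return a [bar_household].
#' @export
simulate_logistic_model <- function(coef, n_days, covariates = list(),
                                    target_id = "Y", seed = NULL) {
  stopifnot(is.numeric(coef), !is.null(names(coef)),
            all(c("a", "pi_b", "pi_d") %in% names(coef)), n_days >= 1)
  T_len <- 96L * as.integer(n_days)
  tau_names <- grep("^tau_", names(coef), value = TRUE)
  sens <- sub("^tau_", "", tau_names)
  covariates <- check_sim_covariates(covariates, T_len, sensor_names = sens)
  grid_start <- if (length(covariates)) covariates[[1]]$grid_start
                else as.POSIXct("2020-01-01", tz = "UTC")
  Z <- if (length(sens))
    vapply(covariates[sens], function(s) as.numeric(s$values), numeric(T_len))
  tau <- unname(coef[tau_names])

  y <- integer(T_len)
  with_seed(seed, {
    u <- stats::runif(T_len)
    for (t in seq_len(T_len)) {
      eta <- coef[["a"]]
      if (t > 1) {
        eta <- eta + coef[["pi_b"]] * y[t - 1]
        if (length(sens)) eta <- eta + sum(tau * Z[t - 1, ])
      }
      if (t >= 97)
        eta <- eta + coef[["pi_d"]] * max(y[max(1, t - 97):(t - 95)])
      y[t] <- as.integer(u[t] < inv_logit(eta))
    }
  })
  assemble_household(
    c(list(bar_series(y, target_id, grid_start = grid_start)), covariates),
    target_id = target_id
  )
}

# align/validate covariate streams handed to a simulator
check_sim_covariates <- function(covariates, T_len, params = NULL,
                                 sensor_names = NULL) {
  if (inherits(covariates, "bar_series")) covariates <- list(covariates)
  if (length(covariates)) {
    nms <- vapply(covariates, function(s) s$sensor_id, character(1))
    names(covariates) <- nms
    for (s in covariates)
      if (length(s$values) != T_len)
        stop(sprintf("covariate '%s' has %d bins; expected %d",
                     s$sensor_id, length(s$values), T_len))
  }
  need <- sensor_names %||% names(params$sensors)
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop(sprintf("missing covariate stream(s): %s", paste(miss, collapse = ", ")))
  covariates
}

#' Reference simulation scenario: sensor X / sensor Y in a small household
#'
#' Packaged generative scenario used by the comparison harness and the
#' examples: a new sensor in a household with one informative "bedroom"
#' covariate (simulated from the two-peak day profile as a stand-in for a
#' real bedroom stream).  `family = "bernoulli_ar"` uses the Bernoulli
#' autoregressive truth (a = -3.3, pi_b = 0.3, phi_b = 0.5, tau = 0.5,
#' psi = 0.9, pi_d = 0.4, phi_d = 0.8); `family = "logistic"` uses the
#' lag-1 logistic truth (a = -2.8, pi_b = 0.8, tau = 1.2, pi_d = 1.4).
#' The horizon is a 31-day training month followed by a 28-day test month.
#'
#' @param family generative model family.
#' @param n_decoys extra independent covariate sensors carrying no signal
#'   (used in selection experiments).
#' @return list describing the scenario: `family`, `bar_params`,
#'   `logistic_coef`, `profiles` (per-covariate day profiles),
#'   `train_days`, `test_days`.
#' @export
scenario_sensor_x <- function(family = c("bernoulli_ar", "logistic"),
                              n_decoys = 0L) {
  family <- match.arg(family)
  profiles <- list(bedroom = day_profile_two_peak())
  if (n_decoys > 0)
    for (i in seq_len(n_decoys))
      profiles[[paste0("decoy", i)]] <- day_profile_two_peak()
  list(
    family = family,
    bar_params = bar_params(a = -3.3, ar = c(0.3, 0.5),
                            sensors = list(bedroom = c(0.5, 0.9)),
                            seasonal = c(0.4, 0.8)),
    logistic_coef = c(a = -2.8, pi_b = 0.8, tau_bedroom = 1.2, pi_d = 1.4),
    profiles = profiles,
    train_days = 31L, test_days = 28L
  )
}

# simulate one train+test replicate of a scenario under one seed
simulate_scenario <- function(scenario, seed = NULL) {
  n_days <- scenario$train_days + scenario$test_days
  with_seed(seed, {
    covs <- lapply(names(scenario$profiles), function(nm)
      simulate_covariate(scenario$profiles[[nm]], n_days, sensor_id = nm))
    names(covs) <- names(scenario$profiles)
    hh <- if (scenario$family == "bernoulli_ar")
      simulate_bar(scenario$bar_params, n_days, covariates = covs)
    else
      simulate_logistic_model(scenario$logistic_coef, n_days, covariates = covs)
    split_at <- 96L * scenario$train_days
    list(train = slice_household(hh, 1, split_at),
         test = slice_household(hh, split_at + 1, hh$T),
         household = hh)
  })
}

#' Replicated forecast-validation comparison of the two models
#'
#' For each replicate: simulate a train month + test month from the
#' scenario's generative truth, fit the Bernoulli autoregressive model
#' (with the truth's block structure) and the logistic baseline on the
#' training month, forecast the test month one step ahead, and count the
#' time-of-day bins whose empirical event count falls outside each model's
#' 95% Poisson-binomial band.  Replicates whose fits fail are dropped with
#' a warning.
#'
#' @param scenario a scenario list as from [scenario_sensor_x()].
#' @param n_reps number of replicates.
#' @param seed master seed; replicate `r` uses `seed + r`.
#' @param models which forecasters to run.
#' @return object of class `bar_comparison`: data.frame `results`
#'   (`rep`, one outside-count column per model), `means`, `n_reps`
#'   (effective).
#' @export
run_comparison <- function(scenario, n_reps = 500L, seed = 1L,
                           models = c("bernoulli_ar", "logistic")) {
  stopifnot(n_reps >= 1)
  models <- match.arg(models, several.ok = TRUE)
  bar_blocks <- c("ar", names(scenario$bar_params$sensors), "seasonal")
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rows[[r]] <- tryCatch({
      sim <- simulate_scenario(scenario, seed = seed + r)
      out <- list(rep = r)
      if ("bernoulli_ar" %in% models) {
        fit <- bar_fit(sim$train, blocks = bar_blocks)
        fc <- forecast_path(fit$params, sim$train, sim$test)
        out$bernoulli_ar <-
          validate_band(sim$test$target, quantile_band(fc))$n_outside
      }
      if ("logistic" %in% models) {
        lfit <- fit_logistic(sim$train)
        lfc <- forecast_logistic(lfit, sim$train, sim$test)
        out$logistic <-
          validate_band(sim$test$target, quantile_band(lfc))$n_outside
      }
      as.data.frame(out)
    }, error = function(e) {
      warning(sprintf("replicate %d dropped: %s", r, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("every replicate failed")
  results <- do.call(rbind, rows)
  structure(
    list(results = results,
         means = colMeans(results[, setdiff(names(results), "rep"), drop = FALSE]),
         n_reps = nrow(results), family = scenario$family),
    class = "bar_comparison"
  )
}

#' @export
print.bar_comparison <- function(x, ...) {
  cat(sprintf("<bar_comparison> truth: %s, %d replicates\n  mean bins outside the 95%% band (of 96):\n",
              x$family, x$n_reps))
  for (nm in names(x$means))
    cat(sprintf("    %-14s %.2f\n", nm, x$means[[nm]]))
  invisible(x)
}
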