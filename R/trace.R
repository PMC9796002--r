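#' Seasonal driver: same-time-yesterday activity with a 45-minute window
#'
#' Routines drift in their timing, so the daily seasonal block is driven by
#' the maximum of the target over a 3-bin window centred one day (96 bins)
#' earlier: `max(y[t-97], y[t-96], y[t-95])`.  Window indices falling before
#' the series start are dropped from the max.
#'
#' @param y a [bar_series] (or plain 0/1 vector).
#' @param t 1-based time index, `t >= 97`.
#' @return 0 or 1.
#' @export
seasonal_driver <- function(y, t) {
  v <- if (inherits(y, "bar_series")) y$values else y
  if (t < 97) stop("seasonal driver undefined before bin 97 (use d_t = 0)")
  idx <- (t - 97):(t - 95)
  idx <- idx[idx >= 1 & idx <= length(v)]
  max(v[idx])
}

# vectorised seasonal driver for t = 97..T; a leading 0 pad stands in for
# the dropped out-of-range index at t = 97
seasonal_driver_vec <- function(y_values) {
  T_len <- length(y_values)
  if (T_len < 97) return(numeric(0))
  t <- 97:T_len
  ypad <- c(0, y_values)
  pmax(ypad[t - 96], y_values[t - 96], y_values[t - 95])
}

# lag-96 geometric recursion x_t = coef * x_{t-96} + input_t, zero-initialised;
# stats::filter runs the recursion in C
lag96_filter <- function(input, coef) {
  as.numeric(stats::filter(input, c(rep(0, 95), coef), method = "recursive"))
}

# lag-1 geometric recursion x_t = coef * x_{t-1} + input_t, zero-initialised
lag1_filter <- function(input, coef) {
  as.numeric(stats::filter(input, coef, method = "recursive"))
}

#' Component trace of the linear predictor
#'
#' Runs the component recursions over a household series and returns every
#' intermediate: the autoregressive component `b_t`, one covariate component
#' `c_{j,t}` per included sensor, the seasonal component `d_t`, the linear
#' predictor `delta_t = a + b_t + sum_j c_{j,t} + d_t`, and the conditional
#' probabilities `p_t = logistic(delta_t)`.  Recursions start from
#' `b_1 = c_{j,1} = 0`, and `d_t = 0` for `t <= 96` (the seasonal window
#' needs a full previous day).
#'
#' @param params a [bar_params]; every sensor named in it must be a
#'   covariate of `data`.
#' @param data a [bar_household].
#' @return object of class `bar_trace`: list with `b`, `c` (named list of
#'   vectors, one per included sensor), `d`, `delta`, `p`, all of length
#'   `T`.
#' @export
compute_trace <- function(params, data) {
  stopifnot(inherits(params, "bar_params"), inherits(data, "bar_household"))
  miss <- setdiff(names(params$sensors), names(data$covariates))
  if (length(miss))
    stop(sprintf("params reference sensors absent from household: %s",
                 paste(miss, collapse = ", ")))
  T_len <- data$T
  y <- as.numeric(data$target$values)
  ylag <- c(0, y[-T_len])

  b <- if (is.null(params$ar)) numeric(T_len)
       else lag1_filter(params$ar[1] * ylag, params$ar[2])

  cc <- list()
  for (nm in names(params$sensors)) {
    z <- as.numeric(data$covariates[[nm]]$values)
    zlag <- c(0, z[-T_len])
    cc[[nm]] <- lag1_filter(params$sensors[[nm]][1] * zlag,
                            params$sensors[[nm]][2])
  }

  if (is.null(params$seasonal) || T_len < 97) {
    d <- numeric(T_len)
  } else {
    m <- c(numeric(96), seasonal_driver_vec(y))
    d <- lag96_filter(params$seasonal[1] * m, params$seasonal[2])
  }

  delta <- params$a + b + d
  for (v in cc) delta <- delta + v
  if (any(!is.finite(delta)))
    stop(sprintf("non-finite linear predictor at t = %d",
                 which(!is.finite(delta))[1]))
  structure(list(b = b, c = cc, d = d, delta = delta, p = inv_logit(delta)),
            class = "bar_trace")
}

#' Log-likelihood of the Bernoulli autoregressive model
#'
#' `l(alpha) = sum_t y_t * delta_t - sum_t log(1 + exp(delta_t))`, the
#' Bernoulli log-likelihood under the logit link, evaluated with a
#' softplus so it stays finite for any finite parameters.
#'
#' @inheritParams compute_trace
#' @param trace optional precomputed [compute_trace()] result.
#' @return scalar log-likelihood.
#' @export
bar_loglik <- function(params, data, trace = NULL) {
  tr <- trace %||% compute_trace(params, data)
  y <- as.numeric(data$target$values)
  sum(y * tr$delta) - sum(softplus(tr$delta))
}

#' Analytic gradient of the log-likelihood
#'
#' The chain rule gives `dl/d delta_t = y_t - p_t`; each component's
#' sensitivity to its spike and decay follows its own linear recursion
#' (run, like the components themselves, as a recursive filter).  The
#' coordinate order matches [params_to_vector()]: `a`, `(pi_b, phi_b)`,
#' `(tau_j, psi_j)` per included sensor, `(pi_d, phi_d)`.
#'
#' @inheritParams bar_loglik
#' @return named numeric vector of length [n_params()].
#' @export
bar_gradient <- function(params, data, trace = NULL) {
  tr <- trace %||% compute_trace(params, data)
  T_len <- data$T
  y <- as.numeric(data$target$values)
  r <- y - tr$p  # dl/d delta_t

  g <- sum(r)  # intercept score
  if (!is.null(params$ar)) {
    ylag <- c(0, y[-T_len])
    db_dpi <- lag1_filter(ylag, params$ar[2])
    db_dphi <- lag1_filter(c(0, tr$b[-T_len]), params$ar[2])
    g <- c(g, sum(r * db_dpi), sum(r * db_dphi))
  }
  for (nm in names(params$sensors)) {
    z <- as.numeric(data$covariates[[nm]]$values)
    zlag <- c(0, z[-T_len])
    psi <- params$sensors[[nm]][2]
    dc_dtau <- lag1_filter(zlag, psi)
    dc_dpsi <- lag1_filter(c(0, tr$c[[nm]][-T_len]), psi)
    g <- c(g, sum(r * dc_dtau), sum(r * dc_dpsi))
  }
  if (!is.null(params$seasonal)) {
    phi_d <- params$seasonal[2]
    if (T_len < 97) {
      g <- c(g, 0, 0)
    } else {
      m <- c(numeric(96), seasonal_driver_vec(y))
      dd_dpi <- lag96_filter(m, phi_d)
      dlag96 <- c(numeric(96), tr$d[1:(T_len - 96)])
      dd_dphi <- lag96_filter(dlag96, phi_d)
      g <- c(g, sum(r * dd_dpi), sum(r * dd_dphi))
    }
  }
  stats::setNames(g, param_names(params))
}
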