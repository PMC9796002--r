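#' Lag-1 design matrix for the logistic baseline
#'
#' The comparison model replaces the decaying components with plain lag-1
#' regressors: `delta_t = a + pi_b * y_{t-1} + sum_j tau_j * z_{j,t-1} +
#' pi_d * max(y[t-97], y[t-96], y[t-95])`.  One row per usable time point
#' `t = 97..T` (the seasonal column needs a full previous day), columns in
#' the fixed order intercept, `y_lag1`, covariates (household order),
#' `seasonal`.
#'
#' @param data a [bar_household] with `T >= 98`.
#' @return list with `X` (design matrix, `T - 96` rows), `y` (response
#'   `y_t`), and `t` (the time indices of the rows).
#' @export
build_design <- function(data) {
  stopifnot(inherits(data, "bar_household"))
  T_len <- data$T
  if (T_len < 98) stop("need at least 98 bins (one day plus two) for the lag-1 design")
  t <- 97:T_len
  y <- as.numeric(data$target$values)
  Z <- covariate_matrix(data)
  X <- cbind(intercept = 1, y_lag1 = y[t - 1])
  if (ncol(Z)) {
    Zl <- Z[t - 1, , drop = FALSE]
    colnames(Zl) <- colnames(Z)
    X <- cbind(X, Zl)
  }
  X <- cbind(X, seasonal = seasonal_driver_vec(y))
  list(X = X, y = y[t], t = t)
}

#' Fit the logistic baseline by IRLS
#'
#' Hand-rolled iteratively reweighted least squares (Newton scoring) on the
#' lag-1 design.  Perfect or quasi-separation is detected when a
#' coefficient escapes `[-30, 30]`; the fit then stops with the
#' coefficients capped and a warning.
#'
#' @param data a [bar_household], or a list `(X, y)` as from
#'   [build_design()].
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @return object of class `bar_logistic`: `coef` (named vector: `a`,
#'   `pi_b`, one `tau_*` per covariate, `pi_d`), `loglik`, `n_iter`,
#'   `converged`.
#' @export
fit_logistic <- function(data, max_iter = 100L, tol = 1e-8) {
  des <- if (inherits(data, "bar_household")) build_design(data) else data
  X <- des$X; y <- des$y
  if (length(unique(y)) < 2)
    stop("response is constant: the logistic fit is not identified")
  k <- ncol(X)
  beta <- numeric(k)
  converged <- FALSE
  n_iter <- 0L
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- inv_logit(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, z * sw)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) stop("singular design in the logistic fit")
    if (any(abs(beta_new) > 30)) {
      warning("possible separation in the logistic fit: coefficients capped at |beta| <= 30")
      beta <- pmin(pmax(beta_new, -30), 30)
      capped <- TRUE
      n_iter <- it
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    n_iter <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% beta)
  nm <- c("a", "pi_b",
          if (k > 3) paste0("tau_", colnames(X)[3:(k - 1)]),
          "pi_d")
  structure(
    list(coef = stats::setNames(as.numeric(beta), nm),
         loglik = sum(y * eta) - sum(softplus(eta)),
         n_iter = n_iter, converged = converged || capped,
         columns = colnames(X)),
    class = "bar_logistic"
  )
}

#' @export
print.bar_logistic <- function(x, ...) {
  cat(sprintf("<bar_logistic> log-likelihood %.4f, %d IRLS iterations\n",
              x$loglik, x$n_iter))
  print(round(x$coef, 4))
  invisible(x)
}

#' One-step-ahead forecasts from the logistic baseline
#'
#' Builds the lag-1 design over the concatenated train + test history and
#' returns the fitted probabilities on the test grid, so the result plugs
#' into [stack_by_bin()], [quantile_band()] and [validate_band()]
#' unchanged.
#'
#' @param model a [bar_logistic].
#' @param train,test [bar_household]s as in [forecast_path()]; `train` must
#'   span at least one day.
#' @param burn_in leading forecasts flagged for discarding.
#' @return a [bar_forecast].
#' @export
forecast_logistic <- function(model, train, test, burn_in = 96L) {
  stopifnot(inherits(model, "bar_logistic"))
  if (train$T < 96) stop("train window must span at least one day")
  full <- concat_household(train, test)
  des <- build_design(full)
  if (!identical(colnames(des$X), model$columns))
    stop("household sensors do not match the fitted design")
  p <- inv_logit(as.numeric(des$X %*% model$coef))
  sel <- des$t > train$T
  new_forecast(p[sel], burn_in, test)
}
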