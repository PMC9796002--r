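#' Parameters of the Bernoulli autoregressive sensor model
#'
#' The linear predictor is
#' `delta_t = a + b_t + sum_j c_{j,t} + d_t` where each included component
#' block carries a spike and a geometric decay:
#' `b_t = phi_b * b_{t-1} + pi_b * y_{t-1}` (self-excitation),
#' `c_{j,t} = psi_j * c_{j,t-1} + tau_j * z_{j,t-1}` (other sensors), and
#' `d_t = phi_d * d_{t-96} + pi_d * max(y_{t-97}, y_{t-96}, y_{t-95})`
#' (daily seasonality with a 45-minute tolerance window).  Blocks are
#' optional; the intercept `a` is always present.  All decay rates must
#' satisfy `|decay| < 1` so the geometric memory is summable.
#'
#' @param a intercept (baseline log-odds of triggering).
#' @param ar `NULL`, or `c(pi = spike, phi = decay)` for the autoregressive
#'   block.
#' @param sensors `NULL`, or a named list (names = covariate sensor labels)
#'   of `c(tau = spike, psi = decay)` pairs; only listed sensors enter the
#'   predictor.
#' @param seasonal `NULL`, or `c(pi = spike, phi = decay)` for the daily
#'   seasonal block.
#' @return object of class `bar_params`.
#' @export
bar_params <- function(a, ar = NULL, sensors = NULL, seasonal = NULL) {
  chk_pair <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != 2 || anyNA(x) || !all(is.finite(x)))
      stop(sprintf("%s block must be two finite numbers (spike, decay)", what))
    if (abs(x[2]) >= 1)
      stop(sprintf("%s decay must satisfy |decay| < 1 (got %.3f)", what, x[2]))
    unname(x)
  }
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a))
  if (!is.null(sensors)) {
    if (length(sensors) == 0) {
      sensors <- NULL
    } else {
      if (!is.list(sensors) || is.null(names(sensors)) ||
          any(!nzchar(names(sensors))) || anyDuplicated(names(sensors)))
        stop("`sensors` must be a uniquely named list of (tau, psi) pairs")
      nms <- names(sensors)
      sensors <- lapply(seq_along(sensors), function(j)
        chk_pair(sensors[[j]], paste0("sensor '", nms[j], "'")))
      names(sensors) <- nms
    }
  }
  structure(
    list(a = as.numeric(a), ar = chk_pair(ar, "ar"),
         sensors = sensors, seasonal = chk_pair(seasonal, "seasonal")),
    class = "bar_params"
  )
}

#' @export
print.bar_params <- function(x, ...) {
  cat(sprintf("<bar_params> k = %d\n  a (intercept): %.4f\n", n_params(x), x$a))
  if (!is.null(x$ar))
    cat(sprintf("  ar:        pi_b = %.4f, phi_b = %.4f\n", x$ar[1], x$ar[2]))
  for (nm in names(x$sensors))
    cat(sprintf("  sensor %-10s tau = %.4f, psi = %.4f\n",
                paste0("'", nm, "':"), x$sensors[[nm]][1], x$sensors[[nm]][2]))
  if (!is.null(x$seasonal))
    cat(sprintf("  seasonal:  pi_d = %.4f, phi_d = %.4f\n",
                x$seasonal[1], x$seasonal[2]))
  invisible(x)
}

#' Number of free parameters
#'
#' One for the intercept plus two per included block.
#'
#' @param params a [bar_params].
#' @return integer parameter count `k`.
#' @export
n_params <- function(params) {
  stopifnot(inherits(params, "bar_params"))
  1L + 2L * ((!is.null(params$ar)) + length(params$sensors) +
               (!is.null(params$seasonal)))
}

# block labels in canonical serialization order
param_names <- function(params) {
  nm <- "a"
  if (!is.null(params$ar)) nm <- c(nm, "pi_b", "phi_b")
  for (s in names(params$sensors)) nm <- c(nm, paste0("tau_", s), paste0("psi_", s))
  if (!is.null(params$seasonal)) nm <- c(nm, "pi_d", "phi_d")
  nm
}

# flatten to the optimizer vector.  scale = "natural" keeps decays as-is;
# scale = "unconstrained" maps each decay through atanh so |decay| < 1 is
# enforced by construction and the optimizer is unconstrained.
params_to_vector <- function(params, scale = c("natural", "unconstrained")) {
  scale <- match.arg(scale)
  dec <- if (scale == "unconstrained") atanh else identity
  v <- params$a
  if (!is.null(params$ar)) v <- c(v, params$ar[1], dec(params$ar[2]))
  for (s in params$sensors) v <- c(v, s[1], dec(s[2]))
  if (!is.null(params$seasonal))
    v <- c(v, params$seasonal[1], dec(params$seasonal[2]))
  stats::setNames(v, param_names(params))
}

# inverse of params_to_vector; `template` supplies the block structure
vector_to_params <- function(v, template, scale = c("natural", "unconstrained")) {
  scale <- match.arg(scale)
  dec <- if (scale == "unconstrained") tanh else identity
  i <- 1
  take <- function() { x <- v[[i]]; i <<- i + 1; x }
  a <- take()
  ar <- if (!is.null(template$ar)) c(take(), dec(take()))
  sensors <- NULL
  if (length(template$sensors)) {
    sensors <- lapply(template$sensors, function(s) c(take(), dec(take())))
    names(sensors) <- names(template$sensors)
  }
  seasonal <- if (!is.null(template$seasonal)) c(take(), dec(take()))
  if (i - 1 != length(v)) stop("parameter vector length does not match template")
  bar_params(a, ar = ar, sensors = sensors, seasonal = seasonal)
}

#' Serialize model parameters to JSON
#'
#' Writes a flat named record with block-inclusion implied by field
#' presence; round-trips exactly through [params_from_json()].
#'
#' @param params a [bar_params].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "bar_params"))
  rec <- as.list(params_to_vector(params, "natural"))
  rec <- c(list(model = "bernoulli_ar",
                sensors = as.list(names(params$sensors) %||% character(0))),
           rec)
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Deserialize model parameters from JSON
#'
#' @param x JSON string or file path produced by [params_to_json()].
#' @return a [bar_params].
#' @export
params_from_json <- function(x) {
  rec <- jsonlite::fromJSON(x)
  if (!identical(rec$model, "bernoulli_ar"))
    stop("not a bernoulli_ar parameter record")
  sens <- NULL
  if (length(rec$sensors)) {
    sens <- lapply(rec$sensors, function(s)
      c(rec[[paste0("tau_", s)]], rec[[paste0("psi_", s)]]))
    names(sens) <- rec$sensors
  }
  bar_params(
    a = rec$a,
    ar = if (!is.null(rec$pi_b)) c(rec$pi_b, rec$phi_b),
    sensors = sens,
    seasonal = if (!is.null(rec$pi_d)) c(rec$pi_d, rec$phi_d)
  )
}
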