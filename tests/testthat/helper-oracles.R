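# Independent oracles and fixture builders.  Everything here is written
# deliberately slowly (explicit loops, direct sums) so it shares no code
# path with the implementation it checks.

MIDNIGHT <- as.POSIXct("2020-01-01", tz = "UTC")

mk_series <- function(values, id = "y", start = MIDNIGHT) {
  bar_series(values, id, grid_start = start)
}

# random 0/1 series with a given activity rate
rand_series <- function(T_len, id = "y", rate = 0.15) {
  mk_series(rbinom(T_len, 1, rate), id = id)
}

# random household with J covariates
rand_household <- function(T_len, J = 2, rate = 0.15) {
  ids <- c("y", if (J > 0) paste0("z", seq_len(J)))
  assemble_household(lapply(ids, function(id) rand_series(T_len, id, rate)),
                     target_id = "y")
}

# random full-block parameters with decays safely inside (-1, 1)
rand_params <- function(J = 2, sensor_names = paste0("z", seq_len(J))) {
  pair <- function() c(runif(1, -1.5, 1.5), runif(1, -0.9, 0.9))
  sens <- if (J > 0) {
    out <- replicate(J, pair(), simplify = FALSE)
    names(out) <- sensor_names
    out
  }
  bar_params(a = runif(1, -4, 0), ar = pair(), sensors = sens, seasonal = pair())
}

# --- closed-form component sums (geometric unrolling of the recursions) ---

oracle_b <- function(pi_b, phi_b, y) {
  T_len <- length(y)
  b <- numeric(T_len)
  for (t in seq_len(T_len)) {
    if (t == 1) next
    i <- seq_len(t - 1)
    b[t] <- pi_b * sum(phi_b^(i - 1) * y[t - i])
  }
  b
}

oracle_seasonal_m <- function(y, t) {
  idx <- (t - 97):(t - 95)
  idx <- idx[idx >= 1 & idx <= length(y)]
  max(y[idx])
}

oracle_d <- function(pi_d, phi_d, y) {
  T_len <- length(y)
  d <- numeric(T_len)
  for (t in seq_len(T_len)) {
    if (t < 97) next
    s <- 0
    i <- 1
    while (t - 96 * i >= 1) {
      u <- t - 96 * (i - 1)  # driver index of the i-th term
      if (u >= 97) s <- s + phi_d^(i - 1) * oracle_seasonal_m(y, u)
      i <- i + 1
    }
    d[t] <- pi_d * s
  }
  d
}

# generic Bernoulli log-likelihood sum(y log p + (1-y) log(1-p))
oracle_bernoulli_ll <- function(y, p) {
  sum(y * log(p) + (1 - y) * log1p(-p))
}

# central finite differences of the log-likelihood on the natural scale
fd_gradient <- function(params, data, h = 1e-6) {
  v <- barsense:::params_to_vector(params, "natural")
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    up <- v; up[i] <- up[i] + h
    dn <- v; dn[i] <- dn[i] - h
    g[i] <- (bar_loglik(barsense:::vector_to_params(up, params), data) -
               bar_loglik(barsense:::vector_to_params(dn, params), data)) / (2 * h)
  }
  setNames(g, names(v))
}

# exact Poisson-binomial pmf by enumeration over all 2^n outcomes
enum_poisson_binomial <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + pr
  }
  pmf
}
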