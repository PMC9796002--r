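#' Maximum-likelihood fit of the Bernoulli autoregressive model
#'
#' Maximizes the log-likelihood by BFGS on an unconstrained
#' reparameterization (decays pass through `tanh` so `|decay| < 1` always
#' holds).  At every iteration the quasi-Newton direction is normalized to
#' unit length and tried at each of six candidate step sizes; the step with
#' the largest log-likelihood is taken (ties go to the smallest step), so
#' the likelihood trajectory is non-decreasing by construction.  The
#' optimizer stops when the log-likelihood improves by less than `tol`,
#' when no candidate step improves it, or at `max_iter` iterations.
#'
#' @param data a [bar_household].
#' @param blocks character vector of component blocks to include: any of
#'   `"ar"`, `"seasonal"`, and covariate sensor labels of `data`.  The
#'   intercept is always included.  Default: all blocks.
#' @param init optional [bar_params] starting point; by default the
#'   intercept starts at `logit(mean(y))` (clipped to `[-8, 8]`), spikes at
#'   0 and decays at 0.5.
#' @param step_sizes candidate step sizes tried at each iteration.
#' @param tol absolute log-likelihood change below which iteration stops.
#' @param max_iter iteration cap.
#' @return object of class `bar_fit`: `params` (a [bar_params]), `loglik`,
#'   `n_iter`, `converged`, `trajectory` (per-iteration log-likelihood),
#'   `k`, and `blocks`.
#' @export
bar_fit <- function(data, blocks = NULL, init = NULL,
                    step_sizes = c(5e-5, 0.01, 0.5, 1, 2.5, 4),
                    tol = 1e-5, max_iter = 500L) {
  stopifnot(inherits(data, "bar_household"))
  covs <- names(data$covariates)
  if (is.null(blocks)) blocks <- c("ar", covs, "seasonal")
  unknown <- setdiff(blocks, c("ar", "seasonal", covs))
  if (length(unknown))
    stop(sprintf("unknown blocks: %s (covariates are: %s)",
                 paste(unknown, collapse = ", "),
                 paste(covs, collapse = ", ")))
  if (anyDuplicated(blocks)) stop("duplicate blocks")

  template <- init %||% default_init(data, blocks)
  if (!setequal(setdiff(param_names(template), "a"), setdiff(param_names(default_init(data, blocks)), "a")))
    stop("`init` block structure does not match `blocks`")

  obj <- make_objective(template, data)
  theta <- params_to_vector(template, "unconstrained")
  res <- bfgs_adaptive(obj$fn, obj$gr, theta, step_sizes = step_sizes,
                       tol = tol, max_iter = max_iter)
  params_hat <- vector_to_params(res$theta, template, "unconstrained")
  structure(
    list(params = params_hat, loglik = res$value, n_iter = res$n_iter,
         converged = res$converged, status = res$status,
         trajectory = res$trajectory, k = n_params(params_hat),
         blocks = blocks),
    class = "bar_fit"
  )
}

#' @export
print.bar_fit <- function(x, ...) {
  cat(sprintf("<bar_fit> log-likelihood %.4f (k = %d), %d iterations (%s)\n",
              x$loglik, x$k, x$n_iter,
              if (x$converged) paste0("converged: ", x$status) else "NOT converged"))
  print(x$params)
  invisible(x)
}

# default start: intercept-only MLE with neutral dynamics
default_init <- function(data, blocks) {
  ybar <- mean(data$target$values)
  a0 <- min(max(stats::qlogis(min(max(ybar, 1e-12), 1 - 1e-12)), -8), 8)
  covs <- intersect(names(data$covariates), blocks)
  sens <- if (length(covs)) {
    stats::setNames(lapply(covs, function(x) c(0, 0.5)), covs)
  }
  bar_params(
    a = a0,
    ar = if ("ar" %in% blocks) c(0, 0.5),
    sensors = sens,
    seasonal = if ("seasonal" %in% blocks) c(0, 0.5)
  )
}

# closures evaluating log-likelihood and its gradient on the unconstrained
# scale; the tanh chain-rule factor (1 - decay^2) converts decay gradients
make_objective <- function(template, data) {
  decay_mask <- grepl("^(phi_|psi_)", param_names(template))
  fn <- function(theta) {
    p <- vector_to_params(theta, template, "unconstrained")
    bar_loglik(p, data)
  }
  gr <- function(theta) {
    p <- vector_to_params(theta, template, "unconstrained")
    g <- bar_gradient(p, data)
    nat <- params_to_vector(p, "natural")
    g[decay_mask] <- g[decay_mask] * (1 - nat[decay_mask]^2)
    g
  }
  list(fn = fn, gr = gr)
}

# BFGS maximizer with a fixed multiset of candidate step sizes applied to
# the unit quasi-Newton direction.  H approximates the inverse Hessian of
# the negated objective; updates violating the curvature condition reset H
# to the identity rather than being damped.
bfgs_adaptive <- function(fn, gr, theta0, step_sizes, tol, max_iter) {
  k <- length(theta0)
  H <- diag(k)
  theta <- theta0
  f <- fn(theta)
  if (!is.finite(f)) stop("objective not finite at the starting point")
  g <- gr(theta)  # gradient of the (maximized) log-likelihood
  trajectory <- f
  status <- "max_iter"
  converged <- FALSE
  n_iter <- 0L
  step_sizes <- sort(step_sizes)

  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(g^2))
    if (!is.finite(gnorm) || gnorm > 1e8)
      stop("gradient blow-up during optimization (norm > 1e8): the likelihood surface is exploding")
    dir <- as.numeric(H %*% g)
    dnorm <- sqrt(sum(dir^2))
    if (dnorm < 1e-14) { status <- "zero_direction"; converged <- TRUE; break }
    u <- dir / dnorm

    cand <- vapply(step_sizes, function(s) {
      v <- fn(theta + s * u)
      if (is.finite(v)) v else -Inf
    }, numeric(1))
    best <- which(cand > f + .Machine$double.eps * abs(f))
    if (!length(best)) { status <- "no_improving_step"; converged <- TRUE; break }
    # largest likelihood wins; among ties (within double eps) the smallest step
    top <- max(cand)
    j <- min(which(cand >= top - .Machine$double.eps * max(1, abs(top))))

    theta_new <- theta + step_sizes[j] * u
    f_new <- cand[j]
    g_new <- gr(theta_new)

    s_vec <- theta_new - theta
    y_vec <- g - g_new  # = grad(-l) difference, the minimization convention
    sy <- sum(s_vec * y_vec)
    if (is.finite(sy) && sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(k)
      V <- I - rho * outer(s_vec, y_vec)
      H <- V %*% H %*% t(V) + rho * outer(s_vec, s_vec)
    } else {
      H <- diag(k)  # curvature condition failed: restart the approximation
    }

    n_iter <- it
    improvement <- f_new - f
    theta <- theta_new; f <- f_new; g <- g_new
    trajectory <- c(trajectory, f)
    if (improvement < tol) { status <- "tol"; converged <- TRUE; break }
  }
  list(theta = theta, value = f, n_iter = n_iter, converged = converged,
       status = status, trajectory = trajectory)
}
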