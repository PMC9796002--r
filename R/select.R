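#' Bayesian information criterion
#'
#' `BIC = k * ln(T) - 2 * loglik`.  Chosen over AIC because it is the more
#' conservative criterion: with a fit per candidate sensor per household,
#' parsimony keeps the computational and false-discovery cost down.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param T_obs number of observations (the full series length).
#' @return scalar BIC (smaller is better).
#' @export
bic <- function(loglik, k, T_obs) {
  stopifnot(k >= 1, T_obs >= 2)
  k * log(T_obs) - 2 * loglik
}

#' Greedy forward block selection under BIC
#'
#' Starts from the intercept-only model and, at each round, fits every
#' one-block extension (candidate blocks: `"ar"`, `"seasonal"`, and each
#' covariate sensor — each contributing a spike/decay pair, i.e. 2
#' parameters).  The block whose extension has the lowest BIC is added if
#' that BIC improves on the current model's, otherwise selection stops.
#' Accepted fits warm-start from the current parameters.  A candidate whose
#' fit fails is skipped with a warning.
#'
#' @inheritParams bar_fit
#' @return object of class `bar_selection`: `blocks` (chosen, in order of
#'   addition), `bic_path` (BIC after each accepted step, starting with the
#'   intercept-only model), `fit` (the final [bar_fit]).
#' @export
forward_select <- function(data, step_sizes = c(5e-5, 0.01, 0.5, 1, 2.5, 4),
                           tol = 1e-5, max_iter = 500L) {
  stopifnot(inherits(data, "bar_household"))
  candidates <- c("ar", names(data$covariates), "seasonal")

  current <- bar_fit(data, blocks = character(0), step_sizes = step_sizes,
                     tol = tol, max_iter = max_iter)
  current_bic <- bic(current$loglik, current$k, data$T)
  chosen <- character(0)
  bic_path <- current_bic

  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    trial <- lapply(remaining, function(blk) {
      tryCatch(
        bar_fit(data, blocks = c(chosen, blk),
                init = extend_params(current$params, blk, data),
                step_sizes = step_sizes, tol = tol, max_iter = max_iter),
        error = function(e) {
          warning(sprintf("candidate block '%s' skipped: %s", blk,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    })
    ok <- !vapply(trial, is.null, logical(1))
    if (!any(ok)) break
    bics <- vapply(trial[ok], function(f) bic(f$loglik, f$k, data$T), numeric(1))
    best <- which.min(bics)
    if (bics[best] >= current_bic) break
    current <- trial[ok][[best]]
    current_bic <- bics[best]
    chosen <- c(chosen, remaining[ok][best])
    bic_path <- c(bic_path, current_bic)
  }

  structure(list(blocks = chosen, bic_path = bic_path, fit = current),
            class = "bar_selection")
}

#' @export
print.bar_selection <- function(x, ...) {
  if (length(x$blocks)) {
    cat("<bar_selection> blocks added:", paste(x$blocks, collapse = " -> "), "\n")
  } else {
    cat("<bar_selection> intercept-only model selected\n")
  }
  cat("  BIC path:", paste(sprintf("%.2f", x$bic_path), collapse = " -> "), "\n")
  invisible(x)
}

# warm start: current fitted params plus the new block at its default init
extend_params <- function(params, blk, data) {
  sens <- params$sensors
  ar <- params$ar
  seas <- params$seasonal
  if (blk == "ar") ar <- c(0, 0.5)
  else if (blk == "seasonal") seas <- c(0, 0.5)
  else sens <- c(sens, stats::setNames(list(c(0, 0.5)), blk))
  bar_params(params$a, ar = ar, sensors = sens, seasonal = seas)
}
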