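test_that("seasonal driver takes the 45-minute window max, clamped at the start", {
  y <- integer(200)
  y[2] <- 1L
  s <- mk_series(y)
  # t = 98 looks at y[1:3]
  expect_equal(seasonal_driver(s, 98), 1)
  expect_equal(seasonal_driver(s, 99), 1)   # window y[2:4]
  expect_equal(seasonal_driver(s, 101), 0)  # window y[4:6]
  # t = 97 drops the out-of-range index t-97 = 0 and looks at y[1:2]
  expect_equal(seasonal_driver(s, 97), 1)
  expect_error(seasonal_driver(s, 96), "undefined")
})

test_that("component recursions match their closed-form geometric sums", {
  set.seed(21)
  for (rep in 1:25) {
    T_len <- sample(150:400, 1)
    hh <- rand_household(T_len, J = 1)
    p <- rand_params(J = 1, sensor_names = "z1")
    tr <- compute_trace(p, hh)
    y <- hh$target$values
    expect_equal(tr$b, oracle_b(p$ar[1], p$ar[2], y), tolerance = 1e-10)
    expect_equal(tr$c$z1,
                 oracle_b(p$sensors$z1[1], p$sensors$z1[2],
                          hh$covariates$z1$values),
                 tolerance = 1e-10)
    expect_equal(tr$d, oracle_d(p$seasonal[1], p$seasonal[2], y),
                 tolerance = 1e-10)
  }
})

test_that("memoryless spike and zero-parameter identities hold", {
  hh <- assemble_household(list(mk_series(rep(1L, 10))), "y")
  tr <- compute_trace(bar_params(0, ar = c(1, 0)), hh)
  expect_equal(tr$b, c(0, rep(1, 9)))

  set.seed(22)
  hh2 <- rand_household(200, J = 2)
  tr2 <- compute_trace(bar_params(0), hh2)
  expect_equal(tr2$p, rep(0.5, 200))

  # intercept-only probability at the household-1 bedroom intercept
  tr3 <- compute_trace(bar_params(-3.009), hh2)
  expect_equal(tr3$p[1], 1 / (1 + exp(3.009)), tolerance = 1e-12)
  expect_equal(round(tr3$p[1], 4), 0.0470)
})

test_that("trace stays finite and strictly inside (0,1) for extreme predictors", {
  hh <- assemble_household(list(mk_series(rep(c(1L, 0L), 100))), "y")
  for (a in c(-700, -30, 30, 700)) {
    tr <- compute_trace(bar_params(a), hh)
    expect_true(all(is.finite(tr$delta)))
    expect_true(all(tr$p > 0 & tr$p < 1))
    expect_true(is.finite(bar_loglik(bar_params(a), hh)))
  }
})

test_that("log-likelihood equals the generic Bernoulli form", {
  # fair-coin case: y = (1,0) with delta = 0
  hh <- assemble_household(list(mk_series(c(1L, 0L))), "y")
  expect_equal(bar_loglik(bar_params(0), hh), 2 * log(0.5))

  # all-zero series at a very negative intercept: likelihood approaches 0
  hh0 <- assemble_household(list(mk_series(integer(300))), "y")
  expect_equal(bar_loglik(bar_params(-30), hh0), 0, tolerance = 1e-10)

  set.seed(23)
  for (rep in 1:20) {
    hh <- rand_household(sample(120:300, 1), J = sample(0:2, 1))
    p <- rand_params(J = length(hh$covariates))
    tr <- compute_trace(p, hh)
    expect_equal(bar_loglik(p, hh),
                 oracle_bernoulli_ll(hh$target$values, tr$p),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under covariate permutation", {
  set.seed(24)
  hh <- rand_household(300, J = 3)
  p <- rand_params(J = 3, sensor_names = c("z1", "z2", "z3"))
  p_perm <- bar_params(p$a, ar = p$ar, sensors = p$sensors[c(3, 1, 2)],
                       seasonal = p$seasonal)
  expect_equal(bar_loglik(p, hh), bar_loglik(p_perm, hh))
})

test_that("intercept score is T * (ybar - 1/2) at zero parameters", {
  set.seed(25)
  hh <- rand_household(250, J = 1)
  g <- bar_gradient(bar_params(0), hh)
  expect_equal(unname(g[["a"]]), 250 * (mean(hh$target$values) - 0.5))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(26)
  configs <- list(
    list(J = 0, blocks = "full"),     # ar + seasonal, no sensors
    list(J = 2, blocks = "full"),     # everything
    list(J = 1, blocks = "intercept") # intercept only
  )
  for (cfg in configs) {
    for (rep in 1:5) {
      hh <- rand_household(sample(200:350, 1), J = cfg$J)
      p <- if (cfg$blocks == "intercept") bar_params(runif(1, -3, 0))
           else rand_params(J = cfg$J)
      g <- bar_gradient(p, hh)
      fd <- fd_gradient(p, hh)
      expect_equal(g, fd, tolerance = 1e-5)
    }
  }
})

test_that("parameter JSON serialization round-trips exactly", {
  p <- bar_params(a = -3.325, ar = c(0.77, 0.17),
                  sensors = list(kettle = c(-2.124, 0.31)),
                  seasonal = c(0.637, 0.817))
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  q <- params_from_json(path)
  expect_identical(barsense:::params_to_vector(q, "natural"),
                   barsense:::params_to_vector(p, "natural"))
  expect_equal(names(q$sensors), "kettle")
})
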