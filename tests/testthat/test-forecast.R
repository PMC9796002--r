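test_that("one-step forecast is consistent with the full trace", {
  set.seed(51)
  for (rep in 1:10) {
    T_len <- sample(150:300, 1)
    hh <- rand_household(T_len, J = 1)
    p <- rand_params(J = 1, sensor_names = "z1")
    # trace over the household extended by one arbitrary bin
    ext <- assemble_household(
      list(mk_series(c(hh$target$values, 1L), "y"),
           mk_series(c(hh$covariates$z1$values, 0L), "z1")),
      "y")
    expect_equal(one_step_forecast(p, hh), compute_trace(p, ext)$p[T_len + 1])
  }
})

test_that("intercept-only forecasts ignore history", {
  set.seed(52)
  hh <- rand_household(200, J = 0, rate = 0.4)
  p <- bar_params(-3.3)
  expect_equal(one_step_forecast(p, hh), plogis(-3.3), tolerance = 1e-12)
  expect_equal(round(one_step_forecast(p, hh), 4), 0.0356)
})

test_that("a firing target raises the next forecast when the spike is positive", {
  base <- integer(150)
  p <- bar_params(-3, ar = c(1.2, 0.5))
  hh0 <- assemble_household(list(mk_series(c(base, 0L))), "y")
  hh1 <- assemble_household(list(mk_series(c(base, 1L))), "y")
  expect_gt(one_step_forecast(p, hh1), one_step_forecast(p, hh0))
})

test_that("forecast path equals the trace restricted to the test window", {
  set.seed(53)
  scen <- scenario_sensor_x("bernoulli_ar")
  sim <- barsense:::simulate_scenario(scen, seed = 53)
  fc <- forecast_path(scen$bar_params, sim$train, sim$test)
  full_tr <- compute_trace(scen$bar_params, sim$household)
  expect_equal(fc$p_hat, full_tr$p[(sim$train$T + 1):sim$household$T])
  expect_equal(length(fc$p_hat), 96 * 28)
})

test_that("stacking drops burn-in and partitions the rest by time of day", {
  fc28 <- barsense:::new_forecast(runif(96 * 28), 96L,
                                  list(target = mk_series(integer(96))))
  st <- stack_by_bin(fc28)
  expect_length(st, 96)
  expect_true(all(vapply(st, length, integer(1)) == 27))
  expect_equal(sum(lengths(st)), 96 * 27)

  fc3 <- barsense:::new_forecast(seq_len(96 * 3) / 300, 96L,
                                 list(target = mk_series(integer(96))))
  st3 <- stack_by_bin(fc3)
  expect_true(all(vapply(st3, length, integer(1)) == 2))
  # no loss or duplication: retained values are exactly days 2-3
  expect_equal(sort(unname(unlist(st3))), fc3$p_hat[97:(96 * 3)])

  fc1 <- barsense:::new_forecast(runif(96), 96L,
                                 list(target = mk_series(integer(96))))
  expect_error(stack_by_bin(fc1), "at least 2 days")
})

test_that("Poisson binomial pmf matches enumeration, binomial, and moment formulas", {
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  pmf11 <- poisson_binomial_pmf(c(1, 1))
  expect_equal(pmf11, c(0, 0, 1))

  set.seed(54)
  for (n in c(3, 7, 10)) {
    pr <- runif(n)
    pmf <- poisson_binomial_pmf(pr)
    expect_equal(pmf, enum_poisson_binomial(pr), tolerance = 1e-12)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    k <- 0:n
    expect_equal(sum(k * pmf), sum(pr), tolerance = 1e-10)
    expect_equal(sum(k^2 * pmf) - sum(k * pmf)^2, sum(pr * (1 - pr)),
                 tolerance = 1e-10)
  }
  # identical probabilities collapse to the binomial
  expect_equal(poisson_binomial_pmf(rep(0.3, 15)), dbinom(0:15, 15, 0.3),
               tolerance = 1e-12)
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("quantile band reduces to binomial quantiles for equal probabilities", {
  st <- c(list(rep(0.5, 27)), replicate(95, runif(5), simplify = FALSE))
  band <- quantile_band(st)
  expect_equal(band$lower[1], qbinom(0.025, 27, 0.5))
  expect_equal(band$upper[1], qbinom(0.975, 27, 0.5))
  # all-zero probabilities pin the band at zero
  band0 <- quantile_band(c(list(rep(0, 10)), st[-1]))
  expect_equal(band0$lower[1], 0)
  expect_equal(band0$upper[1], 0)
  # exchangeability: permuting a bin's probabilities leaves its band alone
  set.seed(55)
  pr <- runif(27, 0, 0.3)
  b1 <- quantile_band(c(list(pr), st[-1]))
  b2 <- quantile_band(c(list(sample(pr)), st[-1]))
  expect_equal(b1$lower, b2$lower)
  expect_equal(b1$upper, b2$upper)
})

test_that("validation counts per bin and uses a closed interval", {
  y <- integer(96 * 3)
  y[96 + 1] <- 1L; y[2 * 96 + 1] <- 1L  # bin 1 fires on both counted days
  y[96 + 5] <- 1L                       # bin 5 fires once
  ytest <- mk_series(y)
  stacks <- replicate(96, rep(0.5, 2), simplify = FALSE)
  band <- quantile_band(stacks)  # [0, 2] for every bin
  rep <- validate_band(ytest, band)
  expect_equal(rep$counts[1], 2L)
  expect_equal(rep$counts[5], 1L)
  expect_equal(rep$n_outside, 0L)  # count == upper is inside

  # shrink the band so bin 1 escapes
  band$upper[1] <- 1L
  rep2 <- validate_band(ytest, band)
  expect_equal(rep2$outside_bins, 1L)
  expect_equal(rep2$n_outside, length(rep2$outside_bins))
})
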