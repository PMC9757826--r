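test_that("drift rates combine utility excitation and feedforward inhibition", {
  expect_equal(drift_rates(c(1, 0.5), ffi_params(k = 2, c = 1, theta = 1,
                                                 i0 = 0.1)),
               c(1.1, -0.9))
  # equal utilities: all drifts k*u*(1-c) + i0
  p <- ffi_params(k = 3, c = 0.4, theta = 1, i0 = 0.2)
  expect_equal(drift_rates(rep(0.5, 3), p), rep(3 * 0.5 * 0.6 + 0.2, 3))
  # c = 0: pure race
  p0 <- ffi_params(k = 3, c = 0, theta = 1, i0 = 0.2)
  expect_equal(drift_rates(c(0.2, 0.8), p0), 3 * c(0.2, 0.8) + 0.2)
  expect_error(drift_rates(1, p), "alternatives")
})

test_that("first-passage density matches the closed form and integrates to 1", {
  expect_equal(fpt_density(1, 1, 1), 1 / sqrt(2 * pi))
  expect_equal(fpt_density(c(-1, 0), 1, 1), c(0, 0))
  expect_lt(fpt_density(1e-8, 1, 1), 1e-10)
  grid <- seq(1e-4, 60, by = 1e-4)
  for (mu in c(0.5, 1.5, 3)) {
    y <- fpt_density(grid, mu, 1.2)
    expect_equal(sum((y[-1] + y[-length(y)]) / 2) * 1e-4, 1, tolerance = 1e-4)
  }
})

test_that("first-passage CDF matches hand evaluation and the density integral", {
  expect_equal(fpt_cdf(0, 1, 1), 0)
  expect_equal(fpt_cdf(1, 1, 1), 0.5 + exp(2) * pnorm(-2), tolerance = 1e-10)
  expect_equal(fpt_cdf(1e4, 1, 1), 1, tolerance = 1e-8)
  # numerically stable at large theta * mu
  expect_true(is.finite(fpt_cdf(10, 50, 30)))
  grid <- seq(1e-4, 20, by = 1e-4)
  y <- fpt_density(grid, 1.2, 0.9)
  num_cdf <- c(0, cumsum((y[-1] + y[-length(y)]) / 2) * 1e-4)
  expect_lt(max(abs(num_cdf - fpt_cdf(grid, 1.2, 0.9))), 1e-6)
})

test_that("trialwise FFI likelihood is symmetric and integrates to p(choice)", {
  par <- ffi_params(k = 5, c = 0.5, theta = 1, tnd = 0.2, i0 = 0.5)
  ts <- seq(0.25, 3, by = 0.05)
  l1 <- choice_rt_likelihood(1, ts, c(0.5, 0.5), par)
  l2 <- choice_rt_likelihood(2, ts, c(0.5, 0.5), par)
  expect_equal(l1, l2)
  # integral over decision time equals the choice probability
  ss <- sim_settings(dt = 0.001, tmax = 30)
  grid <- seq(0.001, 30, by = 0.001)
  li <- choice_rt_likelihood(1, grid + par$tnd, c(0.65, 0.45), par)
  p <- choice_probability(c(0.65, 0.45), par, ss)
  expect_equal(sum((li[-1] + li[-length(li)]) / 2) * 0.001, p[1],
               tolerance = 1e-4)
  expect_warning(out <- choice_rt_likelihood(1, 0.1, c(0.5, 0.5), par), "tnd")
  expect_equal(out, 0)
})

test_that("choice probabilities sum to one and increase with own utility", {
  par <- ffi_params(k = 4, c = 0.6, theta = 1.1, i0 = 1)
  ss <- sim_settings(dt = 0.001, tmax = 30)
  expect_equal(choice_probability(c(0.5, 0.5), par, ss), c(0.5, 0.5),
               tolerance = 1e-3)
  p3 <- choice_probability(c(0.6, 0.4, 0.5), par, ss)
  expect_equal(sum(p3), 1, tolerance = 1e-3)
  u_grid <- seq(0.4, 0.9, by = 0.1)
  p_first <- vapply(u_grid, function(u)
    choice_probability(c(u, 0.5), par, ss)[1], numeric(1))
  expect_true(all(diff(p_first) > 0))
})

test_that("conditional mean RT behaves like an inverse-Gaussian mean", {
  ss <- sim_settings(dt = 0.001, tmax = 60)
  # competitor with strongly negative drift: mean time -> theta / mu + tnd
  par <- ffi_params(k = 4, c = 0, theta = 1.2, tnd = 0.3, i0 = 0)
  m <- mean_rt(c(0.75, -2), par, 1, ss)
  expect_equal(m, 1.2 / (4 * 0.75) + 0.3, tolerance = 1e-3)
  # raising the bound strictly increases mean RT
  ms <- vapply(c(0.8, 1.0, 1.2, 1.4), function(th)
    mean_rt(c(0.6, 0.5), ffi_params(k = 5, c = 0.5, theta = th, i0 = 1), 1, ss),
    numeric(1))
  expect_true(all(diff(ms) > 0))
  # symmetric alternatives: equal conditional means
  par2 <- ffi_params(k = 5, c = 0.5, theta = 1, i0 = 1)
  expect_equal(mean_rt(c(0.5, 0.5), par2, 1, ss),
               mean_rt(c(0.5, 0.5), par2, 2, ss), tolerance = 1e-6)
})

test_that("dual-route likelihood is symmetric and conserves probability", {
  par <- dual_route_params(k = 6, fmi = 0, theta = 1, tnd = 0.2, i0 = 0.8)
  ts <- seq(0.25, 3, by = 0.05)
  l1 <- dual_route_likelihood(1, ts, c(0.4, 0.4), par)
  l2 <- dual_route_likelihood(2, ts, c(0.4, 0.4), par)
  expect_equal(l1, l2)
  # four-way race mass sums to 1
  par2 <- dual_route_params(k = 5, fmi = 0.5, theta = 1, i0 = 1)
  p <- dual_route_choice_probability(c(0.5, 0.3, 0.4), par2, available = 1:2,
                                     settings = sim_settings(dt = 0.001,
                                                             tmax = 40))
  expect_equal(sum(p), 1, tolerance = 1e-3)
})

test_that("divisive-normalisation route drifts are scale invariant", {
  par <- dual_route_params(k = 5, fmi = 0.5, theta = 1, i0 = 1)
  d1 <- decoyrace:::dual_route_drifts(c(0.5, 0.3, 0.4), par, available = 1:2)
  d10 <- decoyrace:::dual_route_drifts(10 * c(0.5, 0.3, 0.4), par,
                                       available = 1:2)
  expect_equal(d1$mu_dn, d10$mu_dn)
  expect_false(isTRUE(all.equal(d1$mu, d10$mu)))
})

test_that("the race simulator is reproducible and symmetric", {
  par <- ffi_params(k = 5, c = 0.5, theta = 1, tnd = 0.3, i0 = 1)
  ss <- sim_settings(dt = 0.002, tmax = 10, npaths = 20000, seed = 11)
  a <- simulate_race(c(0.5, 0.5), par, ss)
  b <- simulate_race(c(0.5, 0.5), par, ss)
  expect_identical(a, b)
  f <- mean(a$choice == 1, na.rm = TRUE)
  se <- sqrt(0.25 / nrow(a))
  expect_lt(abs(f - 0.5), 3 * se)
  expect_true(all(a$rt > par$tnd, na.rm = TRUE))
})

test_that("likelihoods are non-negative and log-likelihoods finite after flooring", {
  set.seed(12)
  par <- ffi_params(k = 2, c = 0.9, theta = 2, tnd = 0.1, i0 = 0)
  lk <- choice_rt_likelihood(rep(1:2, 25), runif(50, 0.2, 3),
                             matrix(runif(100, 0.2, 0.9), 50, 2), par)
  expect_true(all(lk >= 0))
  expect_true(all(is.finite(log(pmax(lk, 1e-10)))))
})
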