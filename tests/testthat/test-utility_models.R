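test_that("expected value and additive utility reproduce the worked pairs", {
  expect_equal(expected_value(1, 0.9) - expected_value(1, 0.8), 0.1)
  expect_equal(expected_value(0.3, 0), 0)
  expect_equal(expected_value(0.5, 0.5), 0.25)
  # equal EV differences, unequal attribute-sum AU differences
  d1 <- additive_utility(1, 0.9, convention = "attribute-sum") -
    additive_utility(1, 0.8, convention = "attribute-sum")
  d2 <- additive_utility(0.5, 0.5, convention = "attribute-sum") -
    additive_utility(0.5, 0.3, convention = "attribute-sum")
  expect_equal(d1, 0.1)
  expect_equal(d2, 0.2)
  # weighted-mean convention is half the attribute sum at lambda = 0.5
  expect_equal(additive_utility(1, 0.9, 0.5), 0.95)
  expect_equal(additive_utility(1, 0.9, 0.5) - additive_utility(1, 0.8, 0.5),
               d1 / 2)
  expect_equal(additive_utility(0.4, 0.9, lambda = 1), 0.4)
  expect_error(additive_utility(0.4, 0.9, lambda = 1.2), "lambda")
})

test_that("probability distortions have the stated fixed points", {
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(distort_probability(p, "log-odds", eta = 1, p0 = 0.3), p)
  expect_equal(distort_probability(0.3, "log-odds", eta = 4.2, p0 = 0.3), 0.3)
  # hand-evaluated inverse-S value
  expect_equal(distort_probability(0.5, "kt", tau = 0.61), 0.4206,
               tolerance = 1e-4)
  expect_equal(distort_probability(p, "kt", tau = 1), p)
  expect_warning(out <- distort_probability(c(0, 1), "log-odds", eta = 2),
                 "endpoint")
  expect_equal(out, c(0, 1))
})

test_that("magnitude distortion is a power law on [0, Inf)", {
  x <- c(0, 0.25, 0.5, 1)
  expect_equal(distort_magnitude(x, 1), x)
  expect_equal(distort_magnitude(1, 7.3), 1)
  expect_equal(distort_magnitude(0.25, 0.5), 0.5)
  expect_error(distort_magnitude(-0.1, 1), "x")
  expect_error(distort_magnitude(0.5, 0), "gamma")
})

test_that("selective integration gates by rank with the tie rules", {
  u <- selective_integration_gate(c(0.4, 0.6, 0.2), c(0.8, 0.5, 0.9),
                                  w2 = 0.5, w3 = 0.9, lambda = 0.5)
  expect_equal(u, c(0.30, 0.325, 0.46))
  # w3 = 1: the lowest value in each attribute shrinks to exactly 0
  g <- selective_integration_gate(c(0.4, 0.6, 0.2), c(0.8, 0.5, 0.9),
                                  w2 = 0, w3 = 1, lambda = 1)
  expect_equal(g, c(0.4, 0.6, 0))       # lambda = 1 isolates X'
  # tie for highest: both unchanged, remaining lowest suppressed by w3
  th <- selective_integration_gate(c(0.6, 0.6, 0.2), c(0.5, 0.5, 0.5),
                                   w2 = 0.5, w3 = 0.9, lambda = 1)
  expect_equal(th, c(0.6, 0.6, 0.02))
  # tie for lowest: both suppressed by w3
  tl <- selective_integration_gate(c(0.2, 0.6, 0.2), c(0.5, 0.5, 0.5),
                                   w2 = 0.5, w3 = 0.9, lambda = 1)
  expect_equal(tl, c(0.02, 0.6, 0.02))
  # three-way tie: untouched
  t3 <- selective_integration_gate(c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4),
                                   w2 = 0.5, w3 = 0.9, lambda = 0.5)
  expect_equal(t3, rep(0.4, 3))
  expect_error(selective_integration_gate(c(1, 0), c(0, 1), 0.8, 0.3), "w2")
})

test_that("SI with zero gating reproduces plain additive utility exactly", {
  set.seed(4)
  for (i in 1:10) {
    X <- matrix(runif(30), 10, 3); P <- matrix(runif(30), 10, 3)
    lam <- runif(1)
    expect_identical(selective_integration_gate(X, P, 0, 0, lam),
                     additive_utility(X, P, lam))
  }
})

test_that("SI utilities are monotone non-increasing in the gating weights", {
  set.seed(5)
  X <- matrix(runif(60), 20, 3); P <- matrix(runif(60), 20, 3)
  grid <- seq(0, 1, by = 0.25)
  prev <- NULL
  for (w in grid) {
    u <- selective_integration_gate(X, P, w2 = w * 0.6, w3 = w, lambda = 0.5)
    if (!is.null(prev)) expect_true(all(u <= prev + 1e-12))
    prev <- u
  }
})

test_that("adaptive gain centres on the context and is shift invariant", {
  # value at the context mean with zero bias maps to sigmoid midpoint
  u <- adaptive_gain_transform(c(0.5, 0.5), c(0.2, 0.8), sx = 0.1, bx = 0,
                               lambda = 1)
  expect_equal(u, c(0.5, 0.5))  # lambda = 1: utility is X^AG alone
  xag <- adaptive_gain_transform(c(0.2, 0.5, 0.8), c(0.5, 0.5, 0.5),
                                 sx = 0.1, bx = 0, lambda = 1)
  expect_equal(xag, c(0.0474, 0.5, 0.9526), tolerance = 1e-3)
  shifted <- adaptive_gain_transform(c(0.2, 0.5, 0.8) + 3, c(0.5, 0.5, 0.5),
                                     sx = 0.1, bx = 0, lambda = 1)
  expect_equal(shifted, xag)
  expect_error(adaptive_gain_transform(c(1, 0), c(0, 1), sx = 0), "slope")
})

test_that("divisive normalisation is a scale-invariant simplex projection", {
  expect_equal(divisive_normalize(c(1, 1)), c(0.5, 0.5))
  expect_equal(divisive_normalize(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  set.seed(6)
  for (i in 1:10) {
    u <- runif(3, 0.1, 2)
    k <- runif(1, 0.1, 10)
    expect_equal(divisive_normalize(k * u), divisive_normalize(u))
    expect_equal(sum(divisive_normalize(u)), 1)
  }
  expect_error(divisive_normalize(c(0, 0)), "zero")
})

test_that("EU and PT nest inside the general distortion machinery", {
  # EU: linear probability (tau = 1), free magnitude power
  x <- c(0.3, 0.7); p <- c(0.8, 0.4)
  eu <- distort_magnitude(x, 0.6) * distort_probability(p, "kt", tau = 1)
  expect_equal(eu, x^0.6 * p)
  # PT with tau = 1 and gamma = 1 collapses to EV
  pt <- distort_magnitude(x, 1) * distort_probability(p, "kt", tau = 1)
  expect_equal(pt, expected_value(x, p))
})
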