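make_subject_sim <- function(seed, config = generator_config(seed = 40),
                             lambda = 0.5, beta = 8) {
  tr <- generate_choice_sets(config)
  spec <- model_spec("au", "static")
  simulate_agent(tr, agent_spec(spec, list(lambda = lambda, beta = beta)),
                 seed = seed)
}

test_that("design matrix columns are z-scored with product interactions", {
  sim <- make_subject_sim(1)
  d <- build_design_matrix(sim, basis = "ev", conditions = "both",
                           include_sum = TRUE)
  for (col in c("z_vdiff", "z_dvar", "z_vsum")) {
    expect_lt(abs(mean(d[[col]])), 1e-10)
    expect_equal(stats::sd(d[[col]]), 1, tolerance = 1e-10)
  }
  # interaction is the product of z-scored components, not z(product)
  expect_equal(d$z_inter, d$z_vdiff * d$z_dvar)
  raw_prod <- d$vdiff * d$dvar
  zprod <- (raw_prod - mean(raw_prod)) / stats::sd(raw_prod)
  expect_false(isTRUE(all.equal(d$z_inter, zprod)))
  # crossed effects present in combined designs
  expect_true(all(c("C", "z_vdiff_x_C", "z_dvar_x_C", "z_inter_x_C") %in%
                    names(d)))
})

test_that("a constant distractor column degenerates to zeros and is aliased", {
  sim <- make_subject_sim(2)
  sim$dx[sim$condition == "ternary"] <- 0.5
  sim$dp[sim$condition == "ternary"] <- 0.8
  d <- build_design_matrix(sim, basis = "ev", conditions = "ternary",
                           distractor = "absolute")
  expect_true(all(d$z_dvar == 0))
  expect_warning(g <- fit_weighted_logit(d), "rank-deficient")
  expect_true(is.na(g$coefficients[["z_dvar"]]))
})

test_that("weighted logit matches closed-form saturated fits", {
  d0 <- data.frame(p = c(0.5, 0.5), w = c(10, 10), x = c(0, 1))
  g0 <- fit_weighted_logit(d0, regressors = character(0))
  expect_equal(unname(g0$coefficients[1]), 0, tolerance = 1e-8)
  d1 <- data.frame(p = c(0.731, 0.5), w = c(1000, 1000), x = c(1, 0))
  g1 <- fit_weighted_logit(d1, regressors = "x")
  expect_equal(unname(g1$coefficients[["x"]]), qlogis(0.731), tolerance = 1e-6)
  expect_equal(unname(g1$coefficients[[1]]), 0, tolerance = 1e-8)
  # doubling weights: identical coefficients, SEs shrink by sqrt(2)
  d2 <- d1; d2$w <- d1$w * 2
  g2 <- fit_weighted_logit(d2, regressors = "x")
  expect_equal(g2$coefficients, g1$coefficients, tolerance = 1e-8)
  expect_equal(unname(g1$se[["x"]] / g2$se[["x"]]), sqrt(2), tolerance = 1e-6)
})

test_that("logit coefficients are invariant to affine regressor rescaling", {
  set.seed(30)
  x <- runif(80); y <- runif(80)
  p <- plogis(0.8 * scale(x)[, 1] + 0.4 * scale(y)[, 1])
  w <- rep(20, 80)
  pe <- rbinom(80, 20, p) / 20
  z <- decoyrace:::zscore
  d_raw <- data.frame(p = pe, w = w, a = z(x), b = z(y))
  d_aff <- data.frame(p = pe, w = w, a = z(5 * x - 2), b = z(-0.3 * y + 7))
  g_raw <- fit_weighted_logit(d_raw, regressors = c("a", "b"))
  g_aff <- fit_weighted_logit(d_aff, regressors = c("a", "b"))
  expect_equal(abs(unname(g_raw$coefficients[-1])),
               abs(unname(g_aff$coefficients[-1])), tolerance = 1e-8)
})

test_that("weighted logit recovers known coefficients within its CIs", {
  set.seed(31)
  truth <- c(0.8, 0.4, -0.3)
  hits <- matrix(FALSE, 100, 3)
  for (r in 1:100) {
    x <- matrix(rnorm(150 * 3), 150, 3)
    w <- sample(1:3, 150, replace = TRUE)
    p <- plogis(drop(x %*% truth))
    pe <- rbinom(150, w, p) / w
    d <- data.frame(p = pe, w = w, x1 = x[, 1], x2 = x[, 2], x3 = x[, 3])
    g <- suppressWarnings(fit_weighted_logit(d, regressors = c("x1", "x2", "x3")))
    ci_lo <- g$coefficients[-1] - 1.96 * g$se[-1]
    ci_hi <- g$coefficients[-1] + 1.96 * g$se[-1]
    hits[r, ] <- truth >= ci_lo & truth <= ci_hi
  }
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("group-level t-tests match the direct formula and Holm's rule", {
  set.seed(32)
  coefs <- cbind(a = rnorm(20, 0.5), b = rnorm(20), zero = rep(0, 20))
  out <- group_level_tests(coefs, correction = "none")
  v <- coefs[, "a"]
  expect_equal(out$tests$t[1], mean(v) / (sd(v) / sqrt(20)), tolerance = 1e-12)
  expect_equal(out$tests$t[3], 0)
  expect_equal(out$tests$p[3], 1)
  # Holm step-down on p = (0.01, 0.04) over two tests
  expect_equal(stats::p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  # across-subject correlation plumbing
  out2 <- group_level_tests(coefs, cor_pairs = list(c("a", "b")))
  ref <- suppressWarnings(stats::cor.test(coefs[, "a"], coefs[, "b"],
                                          method = "spearman"))
  expect_equal(out2$correlations$rho, unname(ref$estimate))
})

test_that("permutation bias correction removes only a subject-level constant", {
  t_acc <- c(0.9, 0.7, 0.8, 0.6, 0.75)
  b_acc <- c(0.85, 0.72, 0.78, 0.66, 0.7)
  pc <- permutation_bias_correction(t_acc, b_acc, nperm = 2000, seed = 7)
  # bias approximates the analytic expectation mean(T) - mean(B)
  expect_equal(pc$bias, mean(t_acc) - mean(b_acc), tolerance = 0.02)
  expect_equal(pc$corrected, pc$raw - pc$bias)
  # deterministic under the seed
  pc2 <- permutation_bias_correction(t_acc, b_acc, nperm = 2000, seed = 7)
  expect_identical(pc$bias, pc2$bias)
  # exchangeable null: identical accuracies everywhere
  pc0 <- permutation_bias_correction(rep(0.8, 4), rep(0.8, 4), nperm = 100,
                                     seed = 1)
  expect_equal(pc0$bias, 0)
  expect_equal(pc0$corrected, rep(0, 4))
  expect_error(permutation_bias_correction(0.5, 0.5), "2 matched")
})

test_that("binned maps have the documented geometry and averaging", {
  set.seed(33)
  x1 <- runif(200); x2 <- runif(200)
  m <- binned_map(x1, x2, rep(0.42, 200))
  expect_equal(dim(m), c(71, 71))
  expect_true(all(abs(m - 0.42) < 1e-12, na.rm = TRUE))
  # y increasing in x1, independent of x2: rows monotone along axis 1
  m2 <- binned_map(x1, x2, x1)
  col_ok <- apply(m2, 2, function(cl) all(diff(cl[is.finite(cl)]) >= -1e-12))
  expect_true(all(col_ok))
  # non-default window/step geometry
  m3 <- binned_map(x1, x2, x1, window_quantile = 0.5, step_quantile = 0.05)
  expect_equal(dim(m3), c(11, 11))
})

test_that("the 2x2 decoy table detects a planted interaction", {
  set.seed(34)
  n <- 50
  delta <- 0.05
  rows <- list()
  for (s in 1:n) {
    for (cell in c("H.inferior", "H.superior", "L.inferior", "L.superior")) {
      mu <- switch(cell, H.inferior = delta, H.superior = -delta, 0)
      prox <- if (startsWith(cell, "H")) "closer-to-H" else "closer-to-L"
      dom <- sub("^[HL]\\.", "", cell)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, corrected = rnorm(3, mu, 0.05),
        proximity = prox, dominance = dom)
    }
  }
  dt <- decoy_effect_table(do.call(rbind, rows))
  an <- dt$anova
  expect_lt(an$p[an$effect == "interaction"], 0.001)
  expect_gt(mean(dt$cells[, "H.inferior"]), 0)
  expect_lt(mean(dt$cells[, "H.superior"]), 0)
  # F statistics agree with an independent repeated-measures ANOVA
  long <- do.call(rbind, lapply(1:n, function(s) {
    cm <- dt$cells[s, ]
    data.frame(subject = factor(s),
               prox = factor(rep(c("H", "L"), each = 2)),
               dom = factor(rep(c("inf", "sup"), 2)),
               y = as.numeric(cm))
  }))
  av <- summary(stats::aov(y ~ prox * dom + Error(subject / (prox * dom)),
                           data = long))
  f_int <- av[["Error: subject:prox:dom"]][[1]]["prox:dom", "F value"]
  expect_equal(an$F[an$effect == "interaction"], f_int, tolerance = 1e-8)
  # all-zero input gives zero cell means and zero F
  zero <- do.call(rbind, lapply(1:4, function(s)
    data.frame(subject = s, corrected = rep(0, 4),
               proximity = rep(c("closer-to-H", "closer-to-L"), 2),
               dominance = rep(c("inferior", "superior"), each = 2))))
  dz <- decoy_effect_table(zero)
  expect_true(all(dz$cells == 0))
  expect_true(all(dz$anova$F == 0))
})
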