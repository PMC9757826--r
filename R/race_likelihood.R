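# Analytic choice/RT likelihoods for the feedforward-inhibition (FFI) race
# and the dual-route (mutual inhibition + divisive normalisation) model.
# Each accumulator is a drifting diffusion with unit noise, zero starting
# point and an absorbing bound theta; first-passage times are inverse
# Gaussian, so trialwise likelihoods are closed-form. A Euler-Maruyama
# simulator serves as the stochastic oracle.

#' FFI race parameters
#'
#' @param k Drift sensitivity (> 0): gain on utility information.
#' @param c Feedforward-inhibition strength in `[0, 1]`; `c = 0` is a pure
#'   race, `c = 1` a drift-diffusion model on the utility difference.
#' @param theta Decision bound (> 0), in units of the noise SD.
#' @param tnd Non-decision time in seconds (`>= 0`).
#' @param i0 Baseline drift added to every accumulator.
#' @return List of class `ffi_params`. Noise SD is fixed at 1 and the
#'   starting point at 0 (diffusion measured in noise units).
#' @export
ffi_params <- function(k, c = 0, theta = 1, tnd = 0, i0 = 0) {
  stopifnot(k > 0, c >= 0, c <= 1, theta > 0, tnd >= 0)
  structure(list(k = k, c = c, theta = theta, tnd = tnd, i0 = i0),
            class = "ffi_params")
}

#' Dual-route race parameters
#'
#' @param k Drift sensitivity (> 0).
#' @param fmi Mutual-inhibition strength.
#' @param theta Decision bound (> 0).
#' @param tnd Non-decision time (s).
#' @param i0 Baseline drift.
#' @return List of class `dual_route_params`. Noise SD fixed at 1.
#' @export
dual_route_params <- function(k, fmi = 0, theta = 1, tnd = 0, i0 = 0) {
  stopifnot(k > 0, theta > 0, tnd >= 0)
  structure(list(k = k, fmi = fmi, theta = theta, tnd = tnd, i0 = i0),
            class = "dual_route_params")
}

#' Integration / simulation settings
#'
#' @param dt Time step in seconds (> 0) for trapezoidal integration and
#'   Euler-Maruyama simulation.
#' @param tmax Integration horizon in seconds.
#' @param npaths Number of simulation paths.
#' @param seed Optional RNG seed for the simulator.
#' @return List of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.001, tmax = 100, npaths = 10000, seed = NULL) {
  stopifnot(dt > 0, tmax > dt, npaths >= 1)
  structure(list(dt = dt, tmax = tmax, npaths = npaths, seed = seed),
            class = "sim_settings")
}

#' FFI drift rates
#'
#' `mu_i = k * U_i - c * k * mean(U_j, j != i) + i0`: each accumulator is
#' excited by its own utility and inhibited by the average utility of the
#' competitors.
#'
#' @param utilities Numeric vector (one choice set) or matrix
#'   (trials x alternatives), `>= 2` alternatives.
#' @param params An [ffi_params()].
#' @return Drift rates, same shape as `utilities`.
#' @export
drift_rates <- function(utilities, params) {
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  n <- ncol(u)
  if (n < 2) stop("drift_rates: need at least 2 alternatives")
  comp_mean <- (rowSums(u) - u) / (n - 1)
  mu <- params$k * u - params$c * params$k * comp_mean + params$i0
  if (is.null(dim(utilities))) drop(mu) else mu
}

#' First-passage-time density of a single accumulator
#'
#' Inverse-Gaussian density of the first crossing of bound `theta` by a
#' diffusion with drift `mu`, unit noise and zero start:
#' `theta / sqrt(2 pi t^3) * exp(-(theta - mu t)^2 / (2 t))`.
#'
#' @param t Decision time(s), seconds; density is 0 for `t <= 0`.
#' @param mu Drift rate.
#' @param theta Bound (> 0).
#' @return Density values.
#' @export
fpt_density <- function(t, mu, theta) {
  stopifnot(all(theta > 0))
  tt <- ifelse(t > 0, t, NA_real_)   # avoid NaN warnings off the support
  out <- theta / sqrt(2 * pi * tt^3) * exp(-(theta - mu * tt)^2 / (2 * tt))
  out[which(t <= 0)] <- 0
  out
}

#' First-passage-time CDF of a single accumulator
#'
#' `Phi((mu T - theta)/sqrt(T)) + exp(2 theta mu) Phi(-(mu T + theta)/sqrt(T))`,
#' with the second term evaluated in log space (log-CDF of the normal) so
#' that large `theta * mu` cannot overflow.
#'
#' @param t Decision time(s) (`>= 0`).
#' @param mu Drift rate.
#' @param theta Bound (> 0).
#' @return Probabilities in `[0, 1]` (0 at `t = 0`; < 1 for negative drift).
#' @export
fpt_cdf <- function(t, mu, theta) {
  stopifnot(all(theta > 0))
  st <- sqrt(pmax(t, 0))
  term1 <- stats::pnorm((mu * t - theta) / st)
  term2 <- exp(2 * theta * mu +
                 stats::pnorm(-(mu * t + theta) / st, log.p = TRUE))
  out <- pmin(pmax(term1 + term2, 0), 1)
  out[which(t <= 0)] <- 0
  out
}

# survival = 1 - cdf, clamped to [0, 1]
fpt_survival <- function(t, mu, theta) pmin(pmax(1 - fpt_cdf(t, mu, theta), 0), 1)

#' Trialwise FFI choice/RT likelihood
#'
#' Density of observing choice `i` at response time `rt`: the first-passage
#' density of accumulator `i` at decision time `T = rt - tnd` times the
#' survival probability of every competitor at `T`. RTs at or below the
#' non-decision time yield zero likelihood with a warning.
#'
#' @param i Chosen alternative index (scalar or per-trial vector).
#' @param rt Response time(s) in seconds.
#' @param utilities Vector (one set) or matrix (trials x alternatives).
#' @param params An [ffi_params()].
#' @return Likelihood density per trial.
#' @export
choice_rt_likelihood <- function(i, rt, utilities, params) {
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  ntr <- max(nrow(u), length(rt), length(i))
  if (nrow(u) == 1 && ntr > 1) u <- u[rep(1, ntr), , drop = FALSE]
  i <- rep_len(i, ntr); rt <- rep_len(rt, ntr)
  mu <- drift_rates(u, params)
  tt <- rt - params$tnd
  bad <- tt <= 0
  if (any(bad)) warning("choice_rt_likelihood: rt <= tnd on ", sum(bad),
                        " trial(s); likelihood set to 0")
  tt[bad] <- NA_real_
  idx <- cbind(seq_len(ntr), i)
  lk <- fpt_density(tt, mu[idx], params$theta)
  for (j in seq_len(ncol(u))) {
    others <- i != j
    if (any(others))
      lk[others] <- lk[others] *
        fpt_survival(tt[others], mu[others, j], params$theta)
  }
  lk[bad] <- 0
  lk
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' FFI choice probabilities by numerical integration
#'
#' Integrates the trialwise likelihood over decision time by the trapezoid
#' rule on the `sim_settings` grid. Warns if mass beyond the horizon exceeds
#' `1e-4`.
#'
#' @param utilities Utility vector of one choice set.
#' @param params An [ffi_params()].
#' @param settings A [sim_settings()].
#' @return Probability vector over alternatives (sums to 1 up to horizon
#'   truncation).
#' @export
choice_probability <- function(utilities, params, settings = sim_settings()) {
  grid <- seq(settings$dt, settings$tmax, by = settings$dt)
  mu <- drift_rates(utilities, params)
  n <- length(utilities)
  dens <- vapply(seq_len(n), function(j) {
    lk <- fpt_density(grid, mu[j], params$theta)
    for (m in seq_len(n)[-j]) lk <- lk * fpt_survival(grid, mu[m], params$theta)
    lk
  }, numeric(length(grid)))
  p <- apply(dens, 2, function(y) trapz(grid, y))
  if (abs(sum(p) - 1) > 1e-4)
    warning(sprintf("choice_probability: probability mass beyond tmax = %.2g",
                    1 - sum(p)))
  p
}

#' Conditional mean response time for one alternative
#'
#' `E(T | choice = i) + tnd`, with the conditional mean computed by
#' trapezoidal integration of `t * L(i, t)` normalised by the choice
#' probability.
#'
#' @inheritParams choice_probability
#' @param i Alternative index.
#' @return Mean RT in seconds.
#' @export
mean_rt <- function(utilities, params, i, settings = sim_settings()) {
  grid <- seq(settings$dt, settings$tmax, by = settings$dt)
  mu <- drift_rates(utilities, params)
  n <- length(utilities)
  lk <- fpt_density(grid, mu[i], params$theta)
  for (m in seq_len(n)[-i]) lk <- lk * fpt_survival(grid, mu[m], params$theta)
  trapz(grid, grid * lk) / trapz(grid, lk) + params$tnd
}

# Drift rates for the two routes of the dual-route model. utilities are the
# (EV) utilities of all alternatives in the choice set (including an
# unavailable distractor, which contributes to both the mutual-inhibition
# mean and the divisive-normalisation denominator). Returns a list with
# matrices mu (vanilla route) and mu_dn for the `available` alternatives.
dual_route_drifts <- function(utilities, params, available = NULL) {
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  if (is.null(available)) available <- seq_len(ncol(u))
  I <- u - params$fmi * rowMeans(u)
  udn <- u / rowSums(u)
  Idn <- udn - params$fmi * rowMeans(udn)
  list(mu = params$k * I[, available, drop = FALSE] + params$i0,
       mu_dn = params$k * Idn[, available, drop = FALSE] + params$i0)
}

#' Trialwise dual-route choice/RT likelihood
#'
#' Two races run simultaneously over the available alternatives: a vanilla
#' mutual-inhibition (MI) race on the raw expected values and an MI race on
#' divisively normalised expected values. The first accumulator (out of all
#' `2 * n_available`) to reach the bound determines the choice, so the
#' likelihood of choice `i` at decision time `T` is the sum over routes of
#' that route's first-passage density for `i` times the survival of every
#' other accumulator in both routes.
#'
#' @param i Chosen available-alternative index (1 = H, 2 = L), scalar or
#'   per-trial.
#' @param rt Response time(s), seconds.
#' @param utilities Expected values: vector (one set) or matrix
#'   (trials x alternatives), including the distractor column on ternary
#'   sets.
#' @param params A [dual_route_params()].
#' @param available Indices of alternatives that accumulate toward a choice
#'   (default: all).
#' @return Likelihood density per trial.
#' @export
dual_route_likelihood <- function(i, rt, utilities, params, available = NULL) {
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  ntr <- max(nrow(u), length(rt), length(i))
  if (nrow(u) == 1 && ntr > 1) u <- u[rep(1, ntr), , drop = FALSE]
  i <- rep_len(i, ntr); rt <- rep_len(rt, ntr)
  dr <- dual_route_drifts(u, params, available)
  nav <- ncol(dr$mu)
  tt <- rt - params$tnd
  bad <- tt <= 0
  if (any(bad)) warning("dual_route_likelihood: rt <= tnd on ", sum(bad),
                        " trial(s); likelihood set to 0")
  tt[bad] <- NA_real_
  idx <- cbind(seq_len(ntr), i)
  theta <- params$theta
  surv_all <- function(except_route, except_alt) {
    s <- rep(1, ntr)
    for (j in seq_len(nav)) {
      if (!(except_route == "mi" && j == except_alt))
        s <- s * fpt_survival(tt, dr$mu[cbind(seq_len(ntr), rep(j, ntr))], theta)
      if (!(except_route == "dn" && j == except_alt))
        s <- s * fpt_survival(tt, dr$mu_dn[cbind(seq_len(ntr), rep(j, ntr))], theta)
    }
    s
  }
  l_mi <- fpt_density(tt, dr$mu[idx], theta)
  l_dn <- fpt_density(tt, dr$mu_dn[idx], theta)
  lk <- rep(0, ntr)
  for (ch in unique(i)) {
    sel <- i == ch
    s_mi <- surv_all("mi", ch)
    s_dn <- surv_all("dn", ch)
    lk[sel] <- l_mi[sel] * s_mi[sel] + l_dn[sel] * s_dn[sel]
  }
  lk[bad] <- 0
  lk
}

#' Dual-route choice probabilities
#'
#' @inheritParams dual_route_likelihood
#' @param settings A [sim_settings()].
#' @return Probability vector over available alternatives.
#' @export
dual_route_choice_probability <- function(utilities, params, available = NULL,
                                          settings = sim_settings()) {
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  dr <- dual_route_drifts(u, params, available)
  nav <- ncol(dr$mu)
  grid <- seq(settings$dt, settings$tmax, by = settings$dt)
  theta <- params$theta
  surv <- lapply(seq_len(nav), function(j)
    list(mi = fpt_survival(grid, dr$mu[1, j], theta),
         dn = fpt_survival(grid, dr$mu_dn[1, j], theta)))
  dens <- lapply(seq_len(nav), function(j)
    list(mi = fpt_density(grid, dr$mu[1, j], theta),
         dn = fpt_density(grid, dr$mu_dn[1, j], theta)))
  p <- vapply(seq_len(nav), function(j) {
    s_mi <- Reduce(`*`, lapply(seq_len(nav), function(m) {
      s <- surv[[m]]$dn
      if (m != j) s <- s * surv[[m]]$mi
      s
    }))
    s_dn <- Reduce(`*`, lapply(seq_len(nav), function(m) {
      s <- surv[[m]]$mi
      if (m != j) s <- s * surv[[m]]$dn
      s
    }))
    trapz(grid, dens[[j]]$mi * s_mi + dens[[j]]$dn * s_dn)
  }, numeric(1))
  if (abs(sum(p) - 1) > 1e-4)
    warning(sprintf("dual_route_choice_probability: mass beyond tmax = %.2g",
                    1 - sum(p)))
  p
}

# Euler-Maruyama first-crossing race over independent accumulators.
# mu: npaths x nacc drift matrix. Returns winner index (NA if censored) and
# decision time. Active paths shrink as they absorb, so cost ~ sum of
# survival times rather than npaths * nsteps. Discrete monitoring misses
# intra-step bound excursions, biasing first-passage times upward by
# O(sqrt(dt)); the Broadie-Glasserman-Kou continuity correction (bound
# shifted inward by 0.5826 * sigma * sqrt(dt)) removes the leading-order
# bias.
em_race <- function(mu, theta, dt, tmax) {
  theta <- theta - 0.5826 * sqrt(dt)
  if (theta <= 0) stop("em_race: bound too small for the chosen dt")
  npaths <- nrow(mu); nacc <- ncol(mu)
  state <- matrix(0, npaths, nacc)
  winner <- rep(NA_integer_, npaths)
  dtime <- rep(NA_real_, npaths)
  active <- seq_len(npaths)
  sddt <- sqrt(dt)
  nsteps <- ceiling(tmax / dt)
  mu_act <- mu
  for (s in seq_len(nsteps)) {
    na <- length(active)
    if (na == 0) break
    state <- state + mu_act * dt +
      matrix(stats::rnorm(na * nacc, sd = sddt), na, nacc)
    crossed <- state >= theta
    hit <- which(rowSums(crossed) > 0)
    if (length(hit)) {
      # ties within a step resolved by the largest overshoot
      over <- state[hit, , drop = FALSE] - theta
      over[!crossed[hit, , drop = FALSE]] <- -Inf
      winner[active[hit]] <- max.col(over, ties.method = "first")
      dtime[active[hit]] <- s * dt
      keep <- setdiff(seq_len(na), hit)
      active <- active[keep]
      state <- state[keep, , drop = FALSE]
      mu_act <- mu_act[keep, , drop = FALSE]
    }
  }
  list(winner = winner, dtime = dtime)
}

#' Simulate the race by Euler-Maruyama integration
#'
#' Stochastic oracle for the analytic likelihoods: integrates
#' `dx_i = mu_i dt + xi sqrt(dt)` with unit-variance Gaussian increments and
#' records the first bound crossing. For `ffi_params` the race runs over the
#' given utilities; for `dual_route_params` both routes' accumulators race
#' and the winning accumulator's alternative is reported.
#'
#' @param utilities Utility vector of one choice set (for the dual-route
#'   model, expected values including any unavailable distractor).
#' @param params An [ffi_params()] or [dual_route_params()].
#' @param settings A [sim_settings()]; `settings$seed` (if non-NULL) makes
#'   the run reproducible.
#' @param available For the dual-route model, indices of alternatives that
#'   can be chosen.
#' @return Data frame with `choice` (alternative index, `NA` when not
#'   absorbed by `tmax`) and `rt` (decision time + `tnd`, `NA` when
#'   censored).
#' @export
simulate_race <- function(utilities, params, settings = sim_settings(),
                          available = NULL) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  np <- settings$npaths
  if (inherits(params, "dual_route_params")) {
    dr <- dual_route_drifts(utilities, params, available)
    nav <- ncol(dr$mu)
    mu <- matrix(c(dr$mu[1, ], dr$mu_dn[1, ]), np, 2 * nav, byrow = TRUE)
    res <- em_race(mu, params$theta, settings$dt, settings$tmax)
    choice <- ifelse(is.na(res$winner), NA_integer_,
                     (res$winner - 1L) %% nav + 1L)
  } else {
    mu1 <- drift_rates(utilities, params)
    mu <- matrix(mu1, np, length(mu1), byrow = TRUE)
    res <- em_race(mu, params$theta, settings$dt, settings$tmax)
    choice <- res$winner
  }
  data.frame(choice = choice, rt = res$dtime + params$tnd)
}
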