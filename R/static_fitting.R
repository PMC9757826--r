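# Model specification, softmax static models, binomial and joint likelihoods,
# multi-start maximum-likelihood fitting, k-fold cross-validation and BIC.

#' Softmax choice probabilities
#'
#' `p(i) = exp(beta * U_i) / sum_j exp(beta * U_j)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param utilities Vector (one set) or matrix (trials x alternatives).
#' @param beta Inverse temperature (`>= 0`).
#' @return Probabilities, same shape as `utilities`; rows sum to 1.
#' @export
softmax_choice_prob <- function(utilities, beta) {
  if (beta < 0 || !is.finite(beta)) stop("softmax_choice_prob: beta must be >= 0")
  u <- if (is.null(dim(utilities))) matrix(utilities, 1) else utilities
  z <- beta * u
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (is.null(dim(utilities))) drop(p) else p
}

#' Weighted binomial log-likelihood of choice proportions
#'
#' `sum w * (pe * log(pm) + (1 - pe) * log(1 - pm))` with model probabilities
#' clipped away from 0 and 1. For integer weights this equals the Bernoulli
#' log-likelihood of the expanded trial-level data.
#'
#' @param p_model Model-predicted probabilities.
#' @param p_empirical Observed proportions in `[0, 1]`.
#' @param weights Observation counts (default 1).
#' @param eps Clipping bound for `p_model`.
#' @return Scalar log-likelihood.
#' @export
binomial_loglik <- function(p_model, p_empirical, weights = 1, eps = 1e-9) {
  if (any(p_empirical < 0 | p_empirical > 1))
    stop("binomial_loglik: empirical proportions must lie in [0, 1]")
  pm <- pmin(pmax(p_model, eps), 1 - eps)
  sum(weights * (p_empirical * log(pm) + (1 - p_empirical) * log(1 - pm)))
}

#' Bayesian information criterion
#'
#' @param ll Maximised log-likelihood.
#' @param nparams Number of free parameters.
#' @param nobs Number of observations.
#' @return `nparams * log(nobs) - 2 * ll`.
#' @export
bic <- function(ll, nparams, nobs) {
  stopifnot(nobs >= 1)
  nparams * log(nobs) - 2 * ll
}

default_param_bounds <- function() {
  list(beta = c(0, 100), lambda = c(0, 1), k = c(1e-3, 40), c = c(0, 1),
       theta = c(0.05, 10), tnd = c(0, 1), i0 = c(0, 10), fmi = c(0, 1),
       w = c(0, 1), w3 = c(0, 1), w2_ratio = c(0, 1),
       gamma = c(0.05, 20), eta = c(0.05, 20), tau = c(0.05, 20),
       p0 = c(0.01, 0.99), sx = c(0.01, 10), bx = c(-1, 1),
       sp = c(0.01, 10), bp = c(-1, 1))
}

#' Specify a choice model
#'
#' Combines a utility family with a response mechanism. Free parameters get
#' finite box bounds; nested models are declared by fixing parameters via
#' `fixed`.
#'
#' @param utility One of [utility_models()]: `"ev"`, `"au"`, `"eu"`, `"pt"`,
#'   `"si"`, `"adaptive_gain"`, `"dn"`.
#' @param dynamics `"static"` (softmax on choice proportions), `"ffi"`
#'   (feedforward-inhibition race on choices and RTs) or `"dual_route"`.
#'   The dual-route mechanism is defined on expected values and ignores
#'   `utility`.
#' @param fixed Named list of parameters to fix (removed from the free set).
#' @param bounds Named list overriding entries of the default bounds.
#' @param si_w `"tied"` fits a single gating weight `w` (`w2 = w3 = w`;
#'   the natural choice for binary trials where only one losing rank
#'   exists); `"ordered"` fits `w3` and the ratio `w2_ratio = w2 / w3`, so
#'   `0 <= w2 <= w3 <= 1` holds throughout optimisation.
#' @param nonlinear If `TRUE`, adds power-law magnitude distortion (`gamma`)
#'   and log-odds probability distortion (`eta`, `p0`) to additive-utility
#'   style families.
#' @param ag_tie If `TRUE`, the adaptive-gain slope/bias are shared across
#'   attributes (frees `sx`, `bx` only).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(utility = "au",
                       dynamics = c("static", "ffi", "dual_route"),
                       fixed = list(), bounds = list(),
                       si_w = c("tied", "ordered"),
                       nonlinear = FALSE, ag_tie = FALSE) {
  dynamics <- match.arg(dynamics)
  si_w <- match.arg(si_w)
  if (dynamics == "dual_route") utility <- "ev"
  if (!utility %in% utility_models()) stop("model_spec: unknown utility family")
  upars <- switch(utility,
    ev = character(0), dn = character(0),
    au = "lambda",
    eu = "gamma",
    pt = c("gamma", "tau"),
    si = c("lambda", if (si_w == "tied") "w" else c("w3", "w2_ratio")),
    adaptive_gain = c("lambda", if (ag_tie) c("sx", "bx")
                      else c("sx", "bx", "sp", "bp")))
  if (nonlinear && utility %in% c("au", "si", "adaptive_gain", "dn"))
    upars <- c(upars, "gamma", "eta", "p0")
  dpars <- switch(dynamics,
    static = "beta",
    ffi = c("k", "c", "theta", "tnd"),
    dual_route = c("k", "fmi", "theta", "tnd"))
  free <- setdiff(c(upars, dpars), names(fixed))
  b <- default_param_bounds()
  b[names(bounds)] <- bounds
  missing_b <- setdiff(free, names(b))
  if (length(missing_b)) stop("model_spec: no bounds for ", paste(missing_b, collapse = ", "))
  structure(list(utility = utility, dynamics = dynamics, free = free,
                 fixed = fixed, bounds = b[free], si_w = si_w,
                 nonlinear = nonlinear, ag_tie = ag_tie),
            class = "model_spec")
}

# merge free values with fixed ones and translate the SI parameterisation
# into the w2/w3 gating weights used by the utility code
spec_pars <- function(spec, values) {
  pars <- c(as.list(values), spec$fixed)
  if (spec$utility == "si") {
    if (!is.null(pars$w)) { pars$w2 <- pars$w; pars$w3 <- pars$w }
    if (!is.null(pars$w2_ratio) && !is.null(pars$w3))
      pars$w2 <- pars$w2_ratio * pars$w3
    if (is.null(pars$w2)) pars$w2 <- pars$w3
    if (is.null(pars$w3)) pars$w3 <- pars$w2
  }
  if (spec$utility == "adaptive_gain" && spec$ag_tie) {
    pars$sp <- pars$sx; pars$bp <- pars$bx
  }
  pars
}

trials_matrices <- function(trials) {
  list(X = cbind(trials$hx, trials$lx, trials$dx),
       P = cbind(trials$hp, trials$lp, trials$dp))
}

included_trials <- function(trials, need_rt = FALSE) {
  ok <- trials$choice %in% c("H", "L")
  if (need_rt) ok <- ok & is.finite(trials$rt)
  ok
}

# static observation model: aggregate to unique conditions
static_conditions <- function(trials) {
  inc <- included_trials(trials)
  df <- as.data.frame(trials)[inc, , drop = FALSE]
  if (!nrow(df)) stop("no trials with H or L choices")
  key <- condition_key(df, c("condition", "hx", "hp", "lx", "lp", "dx", "dp"),
                       digits = 12)
  first <- !duplicated(key)
  agg <- df[first, , drop = FALSE]
  agg$w <- as.vector(table(key)[key[first]])
  agg$pe <- vapply(key[first], function(k)
    mean(df$choice[key == k] == "H"), numeric(1))
  agg
}

#' Joint choice/RT log-likelihood of a dynamic model
#'
#' Sums the log trialwise likelihood ([choice_rt_likelihood()] or
#' [dual_route_likelihood()]) over trials with an H or L response and a
#' valid RT; D choices and non-responses are excluded. Trial likelihoods are
#' floored at `1e-10` before logging.
#'
#' @param trials A `trial_table`.
#' @param spec A [model_spec()] with `ffi` or `dual_route` dynamics.
#' @param params Named vector or list of the spec's free parameter values.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(trials, spec, params) {
  if (spec$dynamics == "static")
    stop("joint_loglik: spec dynamics must be ffi or dual_route")
  inc <- included_trials(trials, need_rt = TRUE)
  if (!any(inc)) stop("joint_loglik: no includable trials")
  df <- as.data.frame(trials)[inc, , drop = FALSE]
  pars <- spec_pars(spec, params)
  m <- trials_matrices(df)
  ch <- ifelse(df$choice == "H", 1L, 2L)
  lk <- if (spec$dynamics == "ffi") {
    u <- compute_utilities(m$X, m$P, spec$utility, pars)
    fp <- ffi_params(k = pars$k, c = if (!is.null(pars$c)) pars$c else 0,
                     theta = pars$theta, tnd = pars$tnd,
                     i0 = if (!is.null(pars$i0)) pars$i0 else 0)
    choice_rt_likelihood(ch, df$rt, u, fp)
  } else {
    ev <- expected_value(m$X, m$P)  # NA distractor column on binary rows
    ev[!is.finite(ev)] <- 0         # absent D contributes nothing to sums
    dp <- dual_route_params(k = pars$k, fmi = pars$fmi, theta = pars$theta,
                            tnd = pars$tnd,
                            i0 = if (!is.null(pars$i0)) pars$i0 else 0)
    tern <- df$condition == "ternary"
    out <- numeric(nrow(df))
    if (any(tern))
      out[tern] <- dual_route_likelihood(ch[tern], df$rt[tern],
                                         ev[tern, , drop = FALSE], dp,
                                         available = 1:2)
    if (any(!tern))
      out[!tern] <- dual_route_likelihood(ch[!tern], df$rt[!tern],
                                          ev[!tern, 1:2, drop = FALSE], dp,
                                          available = 1:2)
    out
  }
  sum(log(pmax(lk, 1e-10)))
}

static_loglik_agg <- function(agg, spec, params) {
  pars <- spec_pars(spec, params)
  m <- trials_matrices(agg)
  u <- compute_utilities(m$X, m$P, spec$utility, pars)
  pm <- softmax_choice_prob(u, pars$beta)[, 1]
  binomial_loglik(pm, agg$pe, agg$w)
}

static_loglik <- function(trials, spec, params) {
  static_loglik_agg(static_conditions(trials), spec, params)
}

#' Log-likelihood of a model on a trial table
#'
#' Dispatches on the spec's dynamics: binomial likelihood of per-condition
#' choice proportions for static specs, joint choice/RT likelihood for
#' dynamic specs.
#'
#' @inheritParams joint_loglik
#' @return Scalar log-likelihood.
#' @export
model_loglik <- function(trials, spec, params) {
  if (spec$dynamics == "static") static_loglik(trials, spec, params)
  else joint_loglik(trials, spec, params)
}

fit_bounds <- function(spec, trials) {
  b <- spec$bounds
  if ("tnd" %in% names(b)) {
    rts <- trials$rt[included_trials(trials, need_rt = TRUE)]
    b$tnd <- c(0, 0.9 * min(rts))
  }
  b
}

#' Fit a model by multi-start maximum likelihood
#'
#' Latin-hypercube starting values over the parameter box, bounded
#' L-BFGS-B optimisation from each start, best run returned. Deterministic
#' given `seed`.
#'
#' @param trials A `trial_table`.
#' @param spec A [model_spec()].
#' @param nstarts Number of random starts (`>= 1`).
#' @param seed RNG seed for the starting grid.
#' @return A list of class `fit_result`: `par` (best free parameters),
#'   `loglik`, `bic`, `nobs`, `nparams`, `starts` (per-start table),
#'   `convergence`, `spec`, `seed`.
#' @export
fit_model <- function(trials, spec, nstarts = 10, seed = 1) {
  stopifnot(nstarts >= 1)
  bounds <- fit_bounds(spec, trials)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  npar <- length(lower)
  nobs <- sum(included_trials(trials, spec$dynamics != "static"))
  agg <- if (spec$dynamics == "static") static_conditions(trials) else NULL
  objective <- function(v) {
    names(v) <- spec$free
    ll <- tryCatch(
      if (is.null(agg)) joint_loglik(trials, spec, v)
      else static_loglik_agg(agg, spec, v),
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  grid <- lhs::randomLHS(nstarts, max(npar, 1))
  starts <- sweep(sweep(grid[, seq_len(npar), drop = FALSE], 2,
                        upper - lower, "*"), 2, lower, "+")
  runs <- vector("list", nstarts)
  for (s in seq_len(nstarts)) {
    runs[[s]] <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(value = Inf, par = starts[s, ],
                               convergence = 99L, message = conditionMessage(e)))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) stop("fit_model: all optimisation starts failed")
  best <- which.min(vals)
  par <- stats::setNames(runs[[best]]$par, spec$free)
  st <- data.frame(start = seq_len(nstarts), negll = vals,
                   convergence = vapply(runs, function(r)
                     as.integer(r$convergence %||% NA_integer_), integer(1)))
  structure(list(par = par, loglik = -vals[best],
                 bic = bic(-vals[best], npar, nobs),
                 nobs = nobs, nparams = npar, starts = st,
                 convergence = runs[[best]]$convergence,
                 spec = spec, seed = seed),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-fold cross-validated log-likelihood
#'
#' Random partition of the trials into `kfolds` folds (stratified by
#' condition type when both binary and ternary trials are present), fitting
#' on the training folds and scoring summed log-likelihood on each held-out
#' fold.
#'
#' @inheritParams fit_model
#' @param kfolds Number of folds (`>= 2`).
#' @return List of class `cv_result`: `fold_loglik`, `cv_loglik` (mean
#'   across folds), `folds` (per-trial assignment), `fits`, `seed`.
#' @export
crossvalidate <- function(trials, spec, kfolds = 5, seed = 1, nstarts = 10) {
  stopifnot(kfolds >= 2, nrow(trials) >= kfolds)
  set.seed(seed)
  folds <- integer(nrow(trials))
  for (cond in unique(trials$condition)) {
    idx <- which(trials$condition == cond)
    folds[idx] <- sample(rep_len(seq_len(kfolds), length(idx)))
  }
  fold_ll <- numeric(kfolds)
  fits <- vector("list", kfolds)
  for (f in seq_len(kfolds)) {
    train <- trials[folds != f, , drop = FALSE]
    test <- trials[folds == f, , drop = FALSE]
    if (!any(included_trials(test, spec$dynamics != "static")))
      stop("crossvalidate: fold ", f, " has no includable trials")
    fit <- fit_model(train, spec, nstarts = nstarts, seed = seed + f)
    fits[[f]] <- fit
    fold_ll[f] <- model_loglik(test, spec, fit$par)
  }
  structure(list(fold_loglik = fold_ll, cv_loglik = mean(fold_ll),
                 folds = folds, fits = fits, seed = seed),
            class = "cv_result")
}
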