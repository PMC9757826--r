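# Static utility functions: expected value, additive utility, non-linear
# attribute distortions, selective integration (rank-dependent gating),
# adaptive gain (context-centred sigmoid), and divisive normalisation.
# All transforms accept matrices with one row per trial and one column per
# alternative, so trialwise likelihoods stay vectorised.

#' Expected value
#'
#' @param x Reward magnitude(s), `>= 0`.
#' @param p Reward probability(ies) in `[0, 1]`.
#' @return `x * p`.
#' @export
expected_value <- function(x, p) {
  if (any(x < 0, na.rm = TRUE)) stop("expected_value: x must be >= 0")
  x * p
}

#' Additive utility
#'
#' Additive (within-attribute) integration of magnitude and probability.
#' Two conventions are supported: the weighted mean
#' `lambda * x + (1 - lambda) * p` (the modelling convention) and the plain
#' attribute sum `x + p` (rank-equivalent at `lambda = 0.5`, differing by a
#' factor of 2; used for worked difference examples).
#'
#' @param x,p Attribute values (vectors or matrices).
#' @param lambda Magnitude weight in `[0, 1]`.
#' @param convention `"weighted-mean"` or `"attribute-sum"`.
#' @return Utilities, same shape as `x`.
#' @export
additive_utility <- function(x, p, lambda = 0.5,
                             convention = c("weighted-mean", "attribute-sum")) {
  convention <- match.arg(convention)
  if (lambda < 0 || lambda > 1) stop("additive_utility: lambda must be in [0, 1]")
  if (convention == "attribute-sum") x + p else lambda * x + (1 - lambda) * p
}

#' Non-linear probability distortion
#'
#' `"log-odds"` mode applies a linear-in-log-odds transform with slope `eta`
#' and fixed point `p0`: `logodds(pd) = eta*logodds(p) + (1-eta)*logodds(p0)`.
#' Endpoints 0 and 1 map to themselves (limit behaviour) with a warning.
#' `"kt"` mode is the one-parameter inverse-S curvature
#' `p^tau / (p^tau + (1-p)^tau)^(1/tau)`.
#'
#' @param p Probabilities.
#' @param mode `"log-odds"` or `"kt"`.
#' @param eta Log-odds slope (> 0).
#' @param p0 Log-odds fixed point in (0, 1).
#' @param tau Curvature (> 0) for `"kt"` mode.
#' @return Distorted probabilities in `[0, 1]`.
#' @export
distort_probability <- function(p, mode = c("log-odds", "kt"),
                                eta = 1, p0 = 0.5, tau = 1) {
  mode <- match.arg(mode)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("distort_probability: p must lie in [0, 1]")
  if (mode == "log-odds") {
    if (eta <= 0) stop("distort_probability: eta must be > 0")
    if (p0 <= 0 || p0 >= 1) stop("distort_probability: p0 must be in (0, 1)")
    out <- p
    interior <- is.finite(p) & p > 0 & p < 1
    if (any(!interior & is.finite(p)))
      warning("distort_probability: endpoint probabilities mapped to themselves")
    lo <- eta * log(p[interior] / (1 - p[interior])) +
      (1 - eta) * log(p0 / (1 - p0))
    out[interior] <- stats::plogis(lo)
    out
  } else {
    if (tau <= 0) stop("distort_probability: tau must be > 0")
    num <- p^tau
    num / (num + (1 - p)^tau)^(1 / tau)
  }
}

#' Power-law magnitude distortion
#'
#' @param x Magnitudes, `>= 0`.
#' @param gamma Power (> 0).
#' @return `x^gamma`.
#' @export
distort_magnitude <- function(x, gamma = 1) {
  if (gamma <= 0) stop("distort_magnitude: gamma must be > 0")
  if (any(x < 0, na.rm = TRUE)) stop("distort_magnitude: x must be >= 0")
  x^gamma
}

# Rank-dependent gating of one attribute across alternatives (rows = trials).
# Highest value untouched; intermediate scaled by (1 - w2); lowest by
# (1 - w3). Tie for highest: both untouched, remaining lowest gated by w3.
# Tie for lowest: both gated by w3. Three-way tie: untouched. With two
# alternatives the lower value is gated by w2 (the single losing rank).
si_gate_attribute <- function(m, w2, w3) {
  n <- ncol(m)
  out <- m
  if (n == 2) {
    lo <- m[, 1] != m[, 2] & m == pmin(m[, 1], m[, 2])
    out[lo] <- out[lo] * (1 - w2)
    return(out)
  }
  if (n != 3) stop("si_gate_attribute: 2 or 3 alternatives supported")
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  all_tie <- mx == mn
  is_max <- m == mx
  is_min <- m == mn & !is_max                  # a maximal value never gated
  n_max <- rowSums(is_max)
  top_tie <- n_max == 2 & !all_tie
  # distinct ranks: intermediate = neither max nor min
  mid <- !is_max & !is_min
  gate3 <- is_min & !all_tie                   # lowest rank(s): (1 - w3)
  gate2 <- mid & !top_tie & !all_tie           # intermediate rank: (1 - w2)
  # ties for lowest: both minima are in is_min, so both get w3; ties for
  # highest leave is_max untouched and the remaining minimum in gate3.
  out[gate2] <- out[gate2] * (1 - w2)
  out[gate3] <- out[gate3] * (1 - w3)
  out
}

#' Selective-integration utilities
#'
#' Within each attribute independently, alternatives are ranked and
#' lower-ranked values are multiplicatively suppressed: the highest value is
#' unchanged, the intermediate is scaled by `1 - w2`, the lowest by `1 - w3`
#' (`0 <= w2 <= w3 <= 1`; `w` is the fractional reduction in processing
#' gain). Ties for the highest leave both untouched; ties for the lowest gate
#' both by `w3`; a full tie leaves the attribute unchanged. The gated
#' attributes are then combined into additive utilities.
#'
#' @param X,P Matrices (trials x alternatives) or vectors (one trial) of
#'   magnitudes and probabilities.
#' @param w2 Gating weight for the intermediate rank, in `[0, 1]`.
#' @param w3 Gating weight for the lowest rank, `w2 <= w3 <= 1`.
#' @param lambda Magnitude weight of the additive utility.
#' @return Matrix (or vector) of utilities per alternative.
#' @export
selective_integration_gate <- function(X, P, w2, w3 = w2, lambda = 0.5) {
  if (w2 < 0 || w3 > 1 || w2 > w3)
    stop("selective_integration_gate: need 0 <= w2 <= w3 <= 1")
  vec <- is.null(dim(X))
  if (vec) { X <- matrix(X, 1); P <- matrix(P, 1) }
  Xg <- si_gate_attribute(X, w2, w3)
  Pg <- si_gate_attribute(P, w2, w3)
  u <- additive_utility(Xg, Pg, lambda)
  if (vec) drop(u) else u
}

#' Adaptive-gain utilities
#'
#' Each attribute value is centred on the context mean across the
#' alternatives in the choice set, passed through a sigmoid
#' `1 / (1 + exp((b - centred) / s))`, and the transformed attributes are
#' combined into additive utilities. Gain control operates independently per
#' attribute with its own slope and bias.
#'
#' @param X,P Matrices (trials x alternatives) or vectors (one trial).
#' @param sx,bx Slope (> 0) and bias for magnitude.
#' @param sp,bp Slope (> 0) and bias for probability.
#' @param lambda Magnitude weight of the additive utility.
#' @return Matrix (or vector) of utilities per alternative.
#' @export
adaptive_gain_transform <- function(X, P, sx, bx = 0, sp = sx, bp = bx,
                                    lambda = 0.5) {
  if (sx <= 0 || sp <= 0) stop("adaptive_gain_transform: slopes must be > 0")
  vec <- is.null(dim(X))
  if (vec) { X <- matrix(X, 1); P <- matrix(P, 1) }
  cx <- X - rowMeans(X)
  cp <- P - rowMeans(P)
  Xag <- stats::plogis((cx - bx) / sx)
  Pag <- stats::plogis((cp - bp) / sp)
  u <- additive_utility(Xag, Pag, lambda)
  if (vec) drop(u) else u
}

#' Divisive normalisation
#'
#' Divides each utility by the sum of utilities across all alternatives in
#' the choice set (rows of a matrix input).
#'
#' @param u Non-negative utilities: vector (one set) or matrix
#'   (trials x alternatives).
#' @return Normalised utilities summing to 1 per choice set.
#' @export
divisive_normalize <- function(u) {
  if (any(u < 0, na.rm = TRUE)) stop("divisive_normalize: utilities must be >= 0")
  if (is.null(dim(u))) {
    s <- sum(u)
    if (s <= 0) stop("divisive_normalize: zero utility sum")
    return(u / s)
  }
  s <- rowSums(u)
  if (any(s <= 0)) stop("divisive_normalize: zero utility sum in some row")
  u / s
}

#' Names of the registered utility model families
#'
#' @return Character vector of family keys accepted by [model_spec()].
#' @export
utility_models <- function() {
  c("ev", "au", "eu", "pt", "si", "adaptive_gain", "dn")
}

# Compute per-alternative utilities for racing alternatives H and L given the
# full choice-set context. X, P: matrices trials x alternatives where column
# 1 = H, 2 = L, 3 = D (D columns NA on binary rows). Context-sensitive
# families (si, adaptive_gain, dn) include D in the context on ternary rows.
# Returns a trials x 2 matrix of utilities for H and L.
compute_utilities <- function(X, P, family, pars) {
  pars <- as.list(pars)
  lam <- if (!is.null(pars$lambda)) pars$lambda else 0.5
  # optional attribute distortions (linear when parameters absent)
  dist_x <- function(x) if (!is.null(pars$gamma)) distort_magnitude(x, pars$gamma) else x
  dist_p <- function(p) {
    if (!is.null(pars$tau)) return(distort_probability(p, "kt", tau = pars$tau))
    if (!is.null(pars$eta))
      return(distort_probability(p, "log-odds", eta = pars$eta,
                                 p0 = if (!is.null(pars$p0)) pars$p0 else 0.5))
    p
  }
  tern <- is.finite(X[, min(3, ncol(X))]) & ncol(X) >= 3
  ctx_utility <- function(fun) {
    # apply a context transform separately to ternary (3 alternatives) and
    # binary (2 alternatives) rows, returning H/L utilities
    u <- matrix(NA_real_, nrow(X), 2)
    if (ncol(X) >= 3 && any(tern)) {
      ut <- fun(X[tern, 1:3, drop = FALSE], P[tern, 1:3, drop = FALSE])
      u[tern, ] <- ut[, 1:2]
    }
    if (any(!tern)) {
      ub <- fun(X[!tern, 1:2, drop = FALSE], P[!tern, 1:2, drop = FALSE])
      u[!tern, ] <- ub
    }
    u
  }
  switch(family,
    ev = expected_value(X[, 1:2], P[, 1:2]),
    au = additive_utility(dist_x(X[, 1:2]), dist_p(P[, 1:2]), lam),
    eu = dist_x(X[, 1:2]) * P[, 1:2],
    pt = dist_x(X[, 1:2]) * distort_probability(P[, 1:2], "kt",
           tau = if (!is.null(pars$tau)) pars$tau else 1),
    si = {
      w2 <- pars$w2; w3 <- if (!is.null(pars$w3)) pars$w3 else pars$w2
      ctx_utility(function(x, p)
        selective_integration_gate(dist_x(x), dist_p(p), w2, w3, lam))
    },
    adaptive_gain = {
      sx <- pars$sx; bx <- if (!is.null(pars$bx)) pars$bx else 0
      sp <- if (!is.null(pars$sp)) pars$sp else sx
      bp <- if (!is.null(pars$bp)) pars$bp else bx
      ctx_utility(function(x, p)
        adaptive_gain_transform(dist_x(x), dist_p(p), sx, bx, sp, bp, lam))
    },
    dn = ctx_utility(function(x, p) divisive_normalize(expected_value(x, p))),
    stop("unknown utility family: ", family)
  )
}
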