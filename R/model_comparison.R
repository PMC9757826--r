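# Random-effects Bayesian model selection over subjects x models evidence,
# with exceedance probabilities by Dirichlet sampling, the Bayes omnibus
# risk, and protected exceedance probabilities; plus model- and
# parameter-recovery harnesses built on the synthetic-data generator.

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Random-effects Bayesian model selection
#'
#' Variational update of a Dirichlet posterior over population model
#' frequencies given per-subject log model evidences (cross-validated
#' log-likelihoods or `-BIC/2`). Exceedance probabilities are estimated by
#' Monte-Carlo sampling from the Dirichlet posterior; the Bayes omnibus risk
#' (BOR) is the posterior probability that model frequencies are all equal,
#' and protected exceedance probabilities apply the chance-level correction
#' `pxp = xp * (1 - BOR) + BOR / K`.
#'
#' @param evidence Numeric matrix, subjects x models, of log model
#'   evidences; finite entries required.
#' @param nsamples Monte-Carlo draws for exceedance estimation.
#' @param seed RNG seed for the sampling step.
#' @param alpha0 Dirichlet prior count per model.
#' @param tol Convergence tolerance on the Dirichlet parameters.
#' @return List of class `bms_result`: `alpha` (Dirichlet parameters),
#'   `frequencies` (posterior mean model frequencies), `assignment`
#'   (subjects x models posterior model attributions), `xp` (exceedance),
#'   `bor`, `pxp` (protected exceedance), `F1`, `F0`.
#' @export
rfx_bms <- function(evidence, nsamples = 1e5, seed = 1, alpha0 = 1,
                    tol = 1e-6) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2) stop("rfx_bms: need at least 2 models")
  if (any(!is.finite(evidence))) {
    cell <- which(!is.finite(evidence), arr.ind = TRUE)[1, ]
    stop(sprintf("rfx_bms: non-finite evidence at subject %d, model %d",
                 cell[1], cell[2]))
  }
  n <- nrow(evidence); K <- ncol(evidence)
  a0 <- rep(alpha0, K)
  alpha <- a0
  g <- matrix(1 / K, n, K)
  for (it in 1:5000) {
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(lw - apply(lw, 1, logsumexp))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  # exceedance by Dirichlet sampling
  set.seed(seed)
  draws <- matrix(stats::rgamma(nsamples * K, shape = rep(alpha, each = nsamples)),
                  nsamples, K)
  xp <- tabulate(max.col(draws, ties.method = "random"), K) / nsamples
  # free energy of the random-effects model vs the null of equal frequencies
  Elogr <- digamma(alpha) - digamma(sum(alpha))
  Sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) - sum((alpha - 1) * Elogr)
  Sqm <- -sum(g[g > 0] * log(g[g > 0]))
  ELJ <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * Elogr) +
    sum(g * sweep(evidence, 2, Elogr, "+"))
  F1 <- ELJ + Sqf + Sqm
  F0 <- sum(apply(evidence, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- xp * (1 - bor) + bor / K
  structure(list(alpha = alpha, frequencies = alpha / sum(alpha),
                 assignment = g, xp = xp, bor = bor, pxp = pxp,
                 F1 = F1, F0 = F0,
                 models = colnames(evidence)),
            class = "bms_result")
}

#' Model recovery by simulate-and-refit
#'
#' For each candidate model, simulates synthetic agents from the supplied
#' generating parameters on the given trial design, refits every candidate
#' model to each simulated dataset, and summarises, per generating model,
#' the random-effects comparison of the fitted models.
#'
#' @param specs Named list of [model_spec()] candidates.
#' @param params_by_model Named list (same names) of data frames: one row of
#'   generating parameters per synthetic agent (columns = the spec's free
#'   parameter names).
#' @param trials Trial design (a `trial_table`; choices/RTs are overwritten
#'   by simulation).
#' @param nstarts Starts per refit.
#' @param seed Seed controlling simulation and refitting.
#' @param evidence `"bic"` scores refits by `-BIC/2` (penalising parameter
#'   count); `"loglik"` uses the raw maximised log-likelihood.
#' @return List of class `confusion_matrix` with matrices `frequencies`
#'   (rows = generating model, posterior model frequencies; rows sum to 1)
#'   and `pxp` (protected exceedance probabilities), plus `fits_evidence`.
#' @export
model_recovery <- function(specs, params_by_model, trials, nstarts = 4,
                           seed = 1, evidence = c("bic", "loglik")) {
  evidence <- match.arg(evidence)
  stopifnot(identical(names(specs), names(params_by_model)))
  K <- length(specs)
  freq <- pxp <- matrix(NA_real_, K, K,
                        dimnames = list(names(specs), names(specs)))
  ev_list <- list()
  for (gi in seq_len(K)) {
    gspec <- specs[[gi]]
    gpar <- params_by_model[[gi]]
    nag <- nrow(gpar)
    emat <- matrix(NA_real_, nag, K, dimnames = list(NULL, names(specs)))
    for (a in seq_len(nag)) {
      agent <- agent_spec(gspec, as.list(gpar[a, , drop = FALSE]))
      sim <- simulate_agent(trials, agent, seed = seed + 1000 * gi + a)
      for (fi in seq_len(K)) {
        fit <- fit_model(sim, specs[[fi]], nstarts = nstarts,
                         seed = seed + 17 * fi + a)
        emat[a, fi] <- if (evidence == "bic") -fit$bic / 2 else fit$loglik
      }
    }
    bms <- rfx_bms(emat, seed = seed + gi)
    freq[gi, ] <- bms$frequencies
    pxp[gi, ] <- bms$pxp
    ev_list[[names(specs)[gi]]] <- emat
  }
  structure(list(frequencies = freq, pxp = pxp, fits_evidence = ev_list),
            class = "confusion_matrix")
}

#' Parameter recovery study
#'
#' Simulates one synthetic agent per row of `true_params` on the given trial
#' design, refits the same model, and summarises recovery per parameter.
#'
#' @param spec A [model_spec()].
#' @param true_params Data frame of generating parameter sets (>= 1 row,
#'   columns = free parameter names).
#' @param trials Trial design to simulate on.
#' @param nstarts Starts per refit.
#' @param seed Seed controlling simulation and refitting.
#' @return List of class `recovery_result`: `table` (long data frame of
#'   true/recovered values) and `summary` (per parameter: correlation, bias,
#'   RMSE).
#' @export
parameter_recovery <- function(spec, true_params, trials, nstarts = 4,
                               seed = 1) {
  nag <- nrow(true_params)
  rec <- true_params[0, , drop = FALSE]
  for (a in seq_len(nag)) {
    agent <- agent_spec(spec, as.list(true_params[a, , drop = FALSE]))
    sim <- simulate_agent(trials, agent, seed = seed + a)
    fit <- fit_model(sim, spec, nstarts = nstarts, seed = seed + 31 * a)
    rec[a, names(true_params)] <- fit$par[names(true_params)]
  }
  long <- do.call(rbind, lapply(names(true_params), function(p)
    data.frame(parameter = p, agent = seq_len(nag),
               true = true_params[[p]], recovered = rec[[p]])))
  summ <- do.call(rbind, lapply(split(long, long$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               correlation = if (stats::sd(d$true) > 0)
                 stats::cor(d$true, d$recovered) else NA_real_,
               bias = mean(d$recovered - d$true),
               rmse = sqrt(mean((d$recovered - d$true)^2)))))
  rownames(summ) <- NULL
  structure(list(table = long, summary = summ), class = "recovery_result")
}
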