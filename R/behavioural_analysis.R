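# Statistical analyses of relative choice accuracy: weighted logistic GLMs
# with z-scored regressors, group-level t-tests with Holm correction,
# permutation-based condition-unspecific bias correction, sliding
# quantile-window binned maps, and the 2x2 decoy-effect analysis.

zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))  # degenerate column
  (v - mean(v)) / s
}

#' Build the relative-accuracy design matrix for one subject
#'
#' Observations are unique ternary conditions. Ternary observations carry
#' the condition's observed relative accuracy; binary observations carry the
#' accuracy of the matched binary trials, inherit the ternary condition's
#' *notional* distractor values, and are weighted by the number of matched
#' binary trials. Regressors (value difference, distractor variable, their
#' interaction, optional value sum) are z-scored before interaction terms
#' are formed; in combined models every effect is crossed with the condition
#' dummy `C` (0 = binary, 1 = ternary).
#'
#' @param trials One subject's `trial_table`.
#' @param basis `"ev"` (expected value) or `"au"` (additive utility).
#' @param lambda Magnitude weight for the AU basis.
#' @param distractor `"relative"` (`DV - HV`) or `"absolute"` (`DV`).
#' @param include_sum Add the value-sum covariate (`HV + LV`).
#' @param conditions `"both"` (T and B with the `C` dummy), `"ternary"`, or
#'   `"binary"` (the notional-distractor design).
#' @param baseline_map Optional precomputed [match_binary_baselines()].
#' @return Data frame of class `design_matrix` with `p` (response
#'   proportion), `w` (observation weight), regressor columns, and
#'   attributes `regressors` (model column names) and `dropped` (count of
#'   unmatched ternary conditions excluded).
#' @export
build_design_matrix <- function(trials, basis = c("ev", "au"), lambda = 0.5,
                                distractor = c("relative", "absolute"),
                                include_sum = FALSE,
                                conditions = c("both", "ternary", "binary"),
                                baseline_map = NULL) {
  basis <- match.arg(basis)
  distractor <- match.arg(distractor)
  conditions <- match.arg(conditions)
  if (is.null(baseline_map)) baseline_map <- match_binary_baselines(trials)
  bm <- baseline_map
  dropped <- sum(!bm$matched)
  if (dropped && conditions != "ternary")
    message("build_design_matrix: ", dropped,
            " unmatched ternary condition(s) excluded")

  val <- function(x, p) switch(basis, ev = x * p,
                               au = additive_utility(x, p, lambda))
  acc_from <- function(rows) {
    ch <- trials$choice[rows]
    n <- sum(ch %in% c("H", "L"))
    c(p = if (n) sum(ch == "H") / n else NA_real_, n = n)
  }

  rows <- list()
  add_obs <- function(cond_row, cvalue, trial_rows) {
    a <- acc_from(trial_rows)
    if (is.na(a["p"]) || a["n"] == 0) return(NULL)
    hv <- val(cond_row$hx, cond_row$hp); lv <- val(cond_row$lx, cond_row$lp)
    dv <- val(cond_row$dx, cond_row$dp)
    data.frame(p = a["p"], w = a["n"], C = cvalue,
               vdiff = hv - lv, vsum = hv + lv,
               dvar = if (distractor == "relative") dv - hv else dv)
  }
  for (i in seq_len(nrow(bm))) {
    cr <- bm[i, ]
    if (conditions != "binary")
      rows[[length(rows) + 1L]] <- add_obs(cr, 1, cr$ternary_rows[[1]])
    if (conditions != "ternary" && cr$matched)
      rows[[length(rows) + 1L]] <- add_obs(cr, 0, cr$binary_rows[[1]])
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || !nrow(d)) stop("build_design_matrix: no usable observations")

  d$z_vdiff <- zscore(d$vdiff)
  d$z_dvar <- zscore(d$dvar)
  d$z_inter <- d$z_vdiff * d$z_dvar   # product of z-scored components
  regs <- c("z_vdiff", "z_dvar", "z_inter")
  if (include_sum) { d$z_vsum <- zscore(d$vsum); regs <- c(regs, "z_vsum") }
  if (conditions == "both") {
    for (r in regs) d[[paste0(r, "_x_C")]] <- d[[r]] * d$C
    regs <- c(regs, "C", paste0(regs, "_x_C"))
  }
  rownames(d) <- NULL
  structure(d, class = c("design_matrix", "data.frame"),
            regressors = regs, dropped = dropped)
}

#' Weighted binomial logit GLM
#'
#' Iteratively reweighted least squares fit of the logit model for the
#' response proportions with observation weights; equivalent to expanded
#' Bernoulli data for integer weights. Aliased (degenerate) columns yield
#' `NA` coefficients; complete separation is flagged.
#'
#' @param design A [build_design_matrix()] result, or any data frame with
#'   `p`, `w` and regressor columns named in `attr(design, "regressors")`.
#' @param regressors Optional character vector overriding the regressor set.
#' @return List of class `glm_result`: `coefficients`, `se`, `converged`,
#'   `separation` (logical), `rank_deficient` (logical), `fit` (the `glm`
#'   object).
#' @export
fit_weighted_logit <- function(design, regressors = NULL) {
  regs <- regressors %||% attr(design, "regressors")
  if (is.null(regs)) regs <- setdiff(names(design), c("p", "w"))
  fml <- stats::as.formula(paste("p ~", paste(c("1", regs), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = as.data.frame(design),
               weights = design$w),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- rep(NA_real_, length(co))
  ok <- !is.na(co)
  se[ok] <- sqrt(diag(stats::vcov(fit)))[names(co)[ok]]
  rank_deficient <- any(!ok)
  if (rank_deficient)
    warning("fit_weighted_logit: rank-deficient design; aliased columns: ",
            paste(names(co)[!ok], collapse = ", "))
  if (separation)
    warning("fit_weighted_logit: possible complete separation")
  structure(list(coefficients = co, se = stats::setNames(se, names(co)),
                 converged = fit$converged, separation = separation,
                 rank_deficient = rank_deficient, fit = fit),
            class = "glm_result")
}

#' Group-level tests of per-subject coefficients
#'
#' Two-sided one-sample t-tests of each coefficient against zero across
#' subjects, with optional Holm step-down correction, plus optional
#' across-subject correlations between pairs of effect estimates.
#'
#' @param coefs Subjects x terms numeric matrix (or data frame).
#' @param correction `"holm"` or `"none"`.
#' @param cor_pairs Optional list of length-2 character vectors naming
#'   coefficient columns to correlate across subjects.
#' @param cor_method `"spearman"` or `"pearson"`.
#' @return List with `tests` (term, mean, t, df, p, p_adj) and
#'   `correlations` (pair, rho, p) when requested. Zero-variance terms get
#'   `NA` statistics.
#' @export
group_level_tests <- function(coefs, correction = c("holm", "none"),
                              cor_pairs = NULL,
                              cor_method = c("spearman", "pearson")) {
  correction <- match.arg(correction)
  cor_method <- match.arg(cor_method)
  coefs <- as.matrix(coefs)
  if (nrow(coefs) < 2) stop("group_level_tests: need >= 2 subjects")
  tests <- do.call(rbind, lapply(colnames(coefs) %||% seq_len(ncol(coefs)),
                                 function(term) {
    v <- coefs[, term]
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 2 || stats::sd(v) == 0) {
      tval <- if (n >= 2 && all(v == 0)) 0 else NA_real_
      pval <- if (!is.na(tval)) 1 else NA_real_
      return(data.frame(term = as.character(term), mean = mean(v), t = tval,
                        df = n - 1, p = pval))
    }
    tt <- stats::t.test(v)
    data.frame(term = as.character(term), mean = mean(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  tests$p_adj <- if (correction == "holm") stats::p.adjust(tests$p, "holm") else tests$p
  rownames(tests) <- NULL
  out <- list(tests = tests)
  if (!is.null(cor_pairs)) {
    out$correlations <- do.call(rbind, lapply(cor_pairs, function(pr) {
      ct <- suppressWarnings(
        stats::cor.test(coefs[, pr[1]], coefs[, pr[2]], method = cor_method))
      data.frame(var1 = pr[1], var2 = pr[2],
                 rho = unname(ct$estimate), p = ct$p.value)
    }))
  }
  out
}

#' Permutation correction for condition-unspecific bias
#'
#' Estimates the generic accuracy change from binary to ternary choice by
#' shuffling the mapping between ternary conditions and their matched binary
#' baselines, and removes this bias from the per-condition T - B contrast.
#'
#' @param ternary_acc Per-condition ternary relative accuracies.
#' @param binary_acc Matched per-condition binary baseline accuracies (same
#'   length/order).
#' @param nperm Number of permutations.
#' @param seed RNG seed.
#' @return List: `bias` (scalar), `corrected` (per-condition bias-corrected
#'   T - B), `raw` (uncorrected T - B).
#' @export
permutation_bias_correction <- function(ternary_acc, binary_acc,
                                        nperm = 5000, seed = 1) {
  stopifnot(length(ternary_acc) == length(binary_acc), nperm >= 1)
  ok <- is.finite(ternary_acc) & is.finite(binary_acc)
  t_acc <- ternary_acc[ok]; b_acc <- binary_acc[ok]
  if (length(t_acc) < 2)
    stop("permutation_bias_correction: need >= 2 matched conditions")
  set.seed(seed)
  perm_means <- vapply(seq_len(nperm), function(i)
    mean(t_acc - b_acc[sample.int(length(b_acc))]), numeric(1))
  bias <- mean(perm_means)
  raw <- ternary_acc - binary_acc
  list(bias = bias, corrected = raw - bias, raw = raw)
}

#' Sliding quantile-window binned map
#'
#' Averages an outcome over a square window sliding through the quantile
#' space of two condition coordinates. With the default 30% window edge and
#' 1% step the grid is 71 x 71.
#'
#' @param x1,x2 Condition coordinates.
#' @param y Outcome to average.
#' @param window_quantile Window edge length as a quantile fraction.
#' @param step_quantile Step size as a quantile fraction.
#' @return Matrix of class `binned_map` (rows follow `x1`, columns `x2`)
#'   with attributes `q1`, `q2` (window lower-edge quantile levels). Empty
#'   cells are `NA`.
#' @export
binned_map <- function(x1, x2, y, window_quantile = 0.30,
                       step_quantile = 0.01) {
  stopifnot(length(x1) == length(x2), length(y) == length(x1))
  if (length(unique(x1)) < 2 || length(unique(x2)) < 2)
    stop("binned_map: need >= 2 distinct values on each axis")
  nbin <- floor((1 - window_quantile) / step_quantile + 1e-9) + 1L
  starts <- (seq_len(nbin) - 1L) * step_quantile
  edges <- function(x) {
    lo <- stats::quantile(x, starts, type = 7, names = FALSE)
    hi <- stats::quantile(x, pmin(starts + window_quantile, 1), type = 7,
                          names = FALSE)
    list(lo = lo, hi = hi)
  }
  e1 <- edges(x1); e2 <- edges(x2)
  m1 <- outer(seq_len(nbin), seq_along(x1),
              function(a, i) x1[i] >= e1$lo[a] & x1[i] <= e1$hi[a])
  m2 <- outer(seq_len(nbin), seq_along(x2),
              function(a, i) x2[i] >= e2$lo[a] & x2[i] <= e2$hi[a])
  num <- m1 %*% (t(m2) * y)
  den <- m1 %*% t(m2)
  map <- num / den
  map[den == 0] <- NA_real_
  structure(map, class = c("binned_map", "matrix"), q1 = starts, q2 = starts)
}

#' Two-by-two decoy-effect table and repeated-measures analysis
#'
#' Averages bias-corrected T - B accuracy contrasts into per-subject 2x2
#' cells (decoy proximity x additive-utility dominance), runs the 2x2
#' repeated-measures ANOVA from orthogonal within-subject contrasts, and
#' tests each cell against zero with Holm correction.
#'
#' @param data Data frame with columns `subject`, `corrected` (bias-corrected
#'   T - B accuracy per condition), `proximity` (`"closer-to-H"` /
#'   `"closer-to-L"`; ties excluded), `dominance` (`"inferior"` /
#'   `"superior"`; `"neither"` excluded).
#' @return List of class `decoy_table`: `cells` (subjects x 4 cell means,
#'   columns `H.inferior`, `H.superior`, `L.inferior`, `L.superior`),
#'   `anova` (proximity, dominance, interaction: F, df, p, partial eta
#'   squared), `cell_tests` (per-cell t-tests, Holm-adjusted), `excluded`
#'   (subjects dropped for empty cells).
#' @export
decoy_effect_table <- function(data) {
  keep <- data$proximity %in% c("closer-to-H", "closer-to-L") &
    data$dominance %in% c("inferior", "superior")
  d <- data[keep, , drop = FALSE]
  d$cell <- paste(ifelse(d$proximity == "closer-to-H", "H", "L"),
                  d$dominance, sep = ".")
  cellnames <- c("H.inferior", "H.superior", "L.inferior", "L.superior")
  subjects <- unique(d$subject)
  cells <- matrix(NA_real_, length(subjects), 4,
                  dimnames = list(as.character(subjects), cellnames))
  for (i in seq_along(subjects)) {
    di <- d[d$subject == subjects[i], ]
    mm <- tapply(di$corrected, di$cell, mean)
    cells[i, names(mm)] <- mm
  }
  complete <- stats::complete.cases(cells)
  excluded <- subjects[!complete]
  if (length(excluded))
    message("decoy_effect_table: ", length(excluded),
            " subject(s) excluded from ANOVA for empty cells")
  cc <- cells[complete, , drop = FALSE]
  if (nrow(cc) < 2) stop("decoy_effect_table: fewer than 2 complete subjects")
  contrast_f <- function(weights) {
    v <- drop(cc %*% weights)
    n <- length(v)
    s <- stats::sd(v)
    tt <- if (s == 0) { if (mean(v) == 0) 0 else Inf }
          else mean(v) / (s / sqrt(n))
    Fv <- tt^2
    data.frame(F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               partial_eta_sq = Fv / (Fv + (n - 1)))
  }
  anova_tab <- rbind(
    proximity = contrast_f(c(0.5, 0.5, -0.5, -0.5)),
    dominance = contrast_f(c(-0.5, 0.5, -0.5, 0.5)),
    interaction = contrast_f(c(-1, 1, 1, -1)))
  anova_tab$effect <- rownames(anova_tab)
  cell_tests <- do.call(rbind, lapply(cellnames, function(cn) {
    v <- cells[, cn]; v <- v[is.finite(v)]
    if (length(v) < 2 || stats::sd(v) == 0)
      return(data.frame(cell = cn, mean = mean(v), t = if (all(v == 0)) 0 else NA,
                        df = length(v) - 1, p = if (all(v == 0)) 1 else NA))
    tt <- stats::t.test(v)
    data.frame(cell = cn, mean = mean(v), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  cell_tests$p_adj <- stats::p.adjust(cell_tests$p, "holm")
  rownames(cell_tests) <- NULL
  structure(list(cells = cells, anova = anova_tab, cell_tests = cell_tests,
                 excluded = excluded),
            class = "decoy_table")
}
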