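# Small in-code fixtures shared across test files.

toy_trials_df <- function() {
  data.frame(
    subject = 1L, trial = 1:4,
    condition = c("binary", "binary", "ternary", "ternary"),
    hx = c(0.8, 0.8, 0.8, 0.6), hp = c(0.7, 0.7, 0.7, 0.9),
    lx = c(0.5, 0.5, 0.5, 0.5), lp = c(0.6, 0.6, 0.6, 0.5),
    dx = c(NA, NA, 0.6, 0.4), dp = c(NA, NA, 0.5, 0.8),
    choice = c("H", "L", "H", "D"),
    rt = c(0.8, 0.9, 1.0, 1.1),
    stringsAsFactors = FALSE)
}

toy_trials <- function() trial_table(toy_trials_df())

write_toy_csv <- function(df = toy_trials_df()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# decoy-geometry design with each ternary condition replicated `reps` times
# (fresh trial ids) so per-condition accuracies are estimable
replicated_decoy_design <- function(reps = 10, bin_reps = 10) {
  fx <- make_fixture("decoy_geometry")
  df <- as.data.frame(fx$trials)
  tern <- df[df$condition == "ternary", ]
  bin <- df[df$condition == "binary", ]
  tern_rep <- tern[rep(seq_len(nrow(tern)), each = reps), ]
  bin_rep <- bin[rep(seq_len(nrow(bin)), each = bin_reps), ]
  out <- rbind(tern_rep, bin_rep)
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(trials = trial_table(out), truth = fx$truth)
}

# per-condition bias-corrected T - B contrasts for one simulated subject
subject_decoy_contrasts <- function(sim, truth, nperm = 200, seed = 1) {
  bm <- match_binary_baselines(sim)
  t_acc <- vapply(bm$ternary_rows, function(r) {
    ch <- sim$choice[r]; n <- sum(ch %in% c("H", "L"))
    if (n) sum(ch == "H") / n else NA_real_
  }, numeric(1))
  b_acc <- vapply(bm$binary_rows, function(r) {
    ch <- sim$choice[r]; n <- sum(ch %in% c("H", "L"))
    if (n) sum(ch == "H") / n else NA_real_
  }, numeric(1))
  pc <- permutation_bias_correction(t_acc, b_acc, nperm = nperm, seed = seed)
  cat_df <- classify_decoy(bm$hx, bm$hp, bm$lx, bm$lp, bm$dx, bm$dp, 0.5)
  data.frame(corrected = pc$corrected, proximity = cat_df$proximity,
             dominance = cat_df$dominance)
}

# direct additive-utility computation for single-trial likelihood checks
compute_utilities_for_test <- function(row, pars) {
  cbind(additive_utility(row$hx, row$hp, pars[["lambda"]]),
        additive_utility(row$lx, row$lp, pars[["lambda"]]))
}
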