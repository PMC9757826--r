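# Data model for two-attribute risky-choice trials: prospects (X, P), choice
# sets with EV-ordered target labels, ternary->binary baseline matching,
# relative accuracy, and decoy classification in the attribute plane.

#' Construct a prospect
#'
#' A prospect is a risky option defined by a reward magnitude `x` and a reward
#' probability `p`, both on normalised `[0, 1]` scales.
#'
#' @param x Reward magnitude, `x >= 0`, finite.
#' @param p Reward probability in `[0, 1]`.
#' @return An object of class `prospect` (named list with `x`, `p`).
#' @examples
#' ev(prospect(0.5, 0.5))  # 0.25
#' @export
prospect <- function(x, p) {
  stopifnot(is.numeric(x), is.numeric(p), length(x) == 1L, length(p) == 1L)
  if (!is.finite(x) || x < 0) stop("prospect: x must be finite and >= 0")
  if (!is.finite(p) || p < 0 || p > 1) stop("prospect: p must lie in [0, 1]")
  structure(list(x = x, p = p), class = "prospect")
}

#' Expected value of a prospect
#'
#' @param p A `prospect`, or a numeric magnitude when `prob` is given.
#' @param prob Optional numeric probability vector (vectorised form).
#' @return `x * p`.
#' @export
ev <- function(p, prob = NULL) {
  if (inherits(p, "prospect")) return(p$x * p$p)
  p * prob
}

#' Default column schema for trial CSV files
#'
#' Maps the canonical column names to file headers and declares the raw
#' attribute ranges used to rescale magnitudes and probabilities onto `[0, 1]`.
#'
#' @param columns Named character vector mapping canonical names
#'   (`subject`, `trial`, `condition`, `hx`, `hp`, `lx`, `lp`, `dx`, `dp`,
#'   `choice`, `rt`) to file column names.
#' @param x_range,p_range Length-2 numeric: raw min/max of the magnitude and
#'   probability columns; values are linearly rescaled to `[0, 1]`.
#' @return A list of class `trial_schema`.
#' @export
trial_schema <- function(columns = NULL, x_range = c(0, 1), p_range = c(0, 1)) {
  canon <- c("subject", "trial", "condition", "hx", "hp", "lx", "lp",
             "dx", "dp", "choice", "rt")
  cols <- stats::setNames(canon, canon)
  if (!is.null(columns)) cols[names(columns)] <- columns
  structure(list(columns = cols, x_range = x_range, p_range = p_range),
            class = "trial_schema")
}

rescale01 <- function(v, range) {
  if (diff(range) == 0) stop("schema range has zero width")
  (v - range[1]) / (range[2] - range[1])
}

#' Assemble and validate a trial table
#'
#' Validates attribute bounds, reassigns H/L labels so that `EV(H) >= EV(L)`
#' on every row, and checks RT admissibility against the choice deadline.
#' Trials with no response (`choice` missing or `"none"`) are kept but flagged.
#'
#' @param df Data frame with columns `subject`, `trial`, `condition`
#'   (`"binary"`/`"ternary"`), `hx`, `hp`, `lx`, `lp`, `dx`, `dp`
#'   (`NA` on binary rows), `choice` (`"H"`, `"L"`, `"D"`, `"none"` or `NA`),
#'   `rt` (seconds, `NA` for no response).
#' @param deadline Choice deadline in seconds (metadata; responded RTs must
#'   satisfy `0 < rt <= deadline`).
#' @return The validated data frame with class `trial_table` and a
#'   `deadline` attribute. Label swaps preserve the choice identity (a row
#'   whose recorded choice was the relabelled option keeps pointing at the
#'   same prospect).
#' @export
trial_table <- function(df, deadline = 1.5) {
  req <- c("subject", "trial", "condition", "hx", "hp", "lx", "lp",
           "dx", "dp", "choice", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trial_table: missing columns: ", paste(miss, collapse = ", "))
  df$condition <- as.character(df$condition)
  if (!all(df$condition %in% c("binary", "ternary")))
    stop("trial_table: condition must be 'binary' or 'ternary'")
  df$choice <- as.character(df$choice)
  df$choice[is.na(df$choice)] <- "none"

  for (col in c("hp", "lp")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad))
      stop(sprintf("trial_table: %s outside [0, 1] at row(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  tern <- df$condition == "ternary"
  if (any(tern)) {
    bad <- which(tern & (!is.finite(df$dx) | !is.finite(df$dp)))
    if (length(bad))
      stop("trial_table: ternary row(s) lacking distractor attributes: ",
           paste(utils::head(bad, 5), collapse = ", "))
    badp <- which(tern & (df$dp < 0 | df$dp > 1))
    if (length(badp))
      stop("trial_table: dp outside [0, 1] at row(s) ",
           paste(utils::head(badp, 5), collapse = ", "))
  }
  df$dx[!tern] <- NA_real_
  df$dp[!tern] <- NA_real_
  for (col in c("hx", "lx")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop(sprintf("trial_table: %s negative or non-finite at row(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
  }

  # enforce EV ordering of target labels
  swap <- df$hx * df$hp < df$lx * df$lp
  if (any(swap)) {
    tmp <- df[swap, c("hx", "hp")]
    df[swap, c("hx", "hp")] <- df[swap, c("lx", "lp")]
    df[swap, c("lx", "lp")] <- tmp
    h2l <- swap & df$choice == "H"
    l2h <- swap & df$choice == "L"
    df$choice[h2l] <- "L"
    df$choice[l2h] <- "H"
  }

  responded <- !(df$choice == "none")
  badrt <- which(responded & (!is.finite(df$rt) | df$rt <= 0 | df$rt > deadline))
  if (length(badrt))
    stop("trial_table: RT missing, non-positive or above deadline at row(s) ",
         paste(utils::head(badrt, 5), collapse = ", "))
  df$rt[!responded] <- NA_real_

  structure(df, class = c("trial_table", "data.frame"), deadline = deadline)
}

#' Load a trial table from CSV
#'
#' Reads a CSV of per-trial attributes, choices and RTs, applies the schema's
#' column mapping and attribute rescaling, and validates via [trial_table()].
#'
#' @param path Path to a CSV file.
#' @param schema A [trial_schema()].
#' @param deadline Choice deadline in seconds.
#' @return A `trial_table`.
#' @export
load_trials <- function(path, schema = trial_schema(), deadline = 1.5) {
  if (!file.exists(path)) stop("load_trials: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- schema$columns
  need <- cols[setdiff(names(cols), c("dx", "dp"))]
  miss <- setdiff(unname(need), names(raw))
  if (length(miss))
    stop("load_trials: schema error, missing column(s): ",
         paste(miss, collapse = ", "))
  df <- data.frame(
    subject = raw[[cols["subject"]]],
    trial = raw[[cols["trial"]]],
    condition = raw[[cols["condition"]]],
    hx = rescale01(raw[[cols["hx"]]], schema$x_range),
    hp = rescale01(raw[[cols["hp"]]], schema$p_range),
    lx = rescale01(raw[[cols["lx"]]], schema$x_range),
    lp = rescale01(raw[[cols["lp"]]], schema$p_range),
    dx = if (cols["dx"] %in% names(raw)) rescale01(raw[[cols["dx"]]], schema$x_range) else NA_real_,
    dp = if (cols["dp"] %in% names(raw)) rescale01(raw[[cols["dp"]]], schema$p_range) else NA_real_,
    choice = raw[[cols["choice"]]],
    rt = raw[[cols["rt"]]],
    stringsAsFactors = FALSE
  )
  trial_table(df, deadline = deadline)
}

condition_key <- function(df, cols, digits = 12) {
  do.call(paste, c(lapply(cols, function(cl) {
    v <- df[[cl]]
    if (is.numeric(v)) formatC(round(v, digits), format = "g", digits = 15)
    else as.character(v)
  }), sep = "|"))
}

#' Match binary baseline trials to ternary conditions
#'
#' Every unique ternary condition (unique `(hx, hp, lx, lp, dx, dp)`) is
#' matched to all binary trials that share its exact target attribute
#' quadruple `(hx, hp, lx, lp)` (up to `tol`). The number of matched binary
#' trials is the condition's observation weight; unmatched conditions are
#' kept with weight 0 and flagged.
#'
#' @param trials A `trial_table` containing both condition types.
#' @param tol Absolute tolerance for attribute equality (float round-trip).
#' @return A data.frame of class `baseline_map`: one row per unique ternary
#'   condition with columns `hx, hp, lx, lp, dx, dp`, `weight` (count of
#'   matched binary trials), `matched` (logical), and a list column
#'   `binary_rows` of matching row indices into `trials`.
#' @export
match_binary_baselines <- function(trials, tol = 1e-9) {
  stopifnot(inherits(trials, "trial_table") || is.data.frame(trials))
  bin <- which(trials$condition == "binary")
  tern <- which(trials$condition == "ternary")
  if (!length(bin)) stop("match_binary_baselines: no binary trials in table")
  if (!length(tern)) stop("match_binary_baselines: no ternary trials in table")

  digits <- max(0L, floor(-log10(tol)))
  tdf <- trials[tern, c("hx", "hp", "lx", "lp", "dx", "dp")]
  tkey <- condition_key(cbind(tdf), c("hx", "hp", "lx", "lp", "dx", "dp"), digits)
  uniq <- !duplicated(tkey)
  out <- tdf[uniq, , drop = FALSE]
  out$ternary_rows <- lapply(tkey[uniq], function(k) tern[tkey == k])

  bkey <- condition_key(trials[bin, c("hx", "hp", "lx", "lp")],
                        c("hx", "hp", "lx", "lp"), digits)
  okey <- condition_key(out, c("hx", "hp", "lx", "lp"), digits)
  out$binary_rows <- lapply(okey, function(k) bin[bkey == k])
  out$weight <- vapply(out$binary_rows, length, integer(1))
  out$matched <- out$weight > 0L
  rownames(out) <- NULL
  structure(out, class = c("baseline_map", "data.frame"))
}

#' Relative choice accuracy per condition
#'
#' The proportion of H choices among trials on which H or L was chosen;
#' D choices and non-responses enter neither numerator nor denominator.
#' Groups without any H/L choice are reported as `NA` with a warning.
#'
#' @param trials A `trial_table` (or compatible data frame).
#' @param by Character vector of grouping columns (default: the attribute
#'   columns defining a unique condition, plus condition type).
#' @return Data frame with the grouping columns, `n_hl` (H-or-L count) and
#'   `p_h_over_l`.
#' @export
relative_accuracy <- function(trials,
                              by = c("condition", "hx", "hp", "lx", "lp", "dx", "dp")) {
  df <- as.data.frame(trials)
  key <- do.call(paste, c(lapply(by, function(cl) {
    v <- df[[cl]]
    ifelse(is.na(v), "NA", format(v, digits = 15))
  }), sep = "|"))
  hl <- df$choice %in% c("H", "L")
  groups <- split(seq_len(nrow(df)), key)
  res <- lapply(groups, function(idx) {
    n <- sum(hl[idx])
    p <- if (n == 0) NA_real_ else sum(df$choice[idx] == "H") / n
    cbind(df[idx[1], by, drop = FALSE],
          data.frame(n_hl = n, p_h_over_l = p))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (anyNA(out$p_h_over_l))
    warning("relative_accuracy: ", sum(is.na(out$p_h_over_l)),
            " group(s) without H/L choices reported as NA")
  out
}

#' Classify a decoy by proximity and additive-utility dominance
#'
#' Proximity is the decoy's relative Euclidean distance to H versus L in the
#' normalised `(X, P)` attribute plane. Dominance compares the decoy's
#' additive utility (weighted mean, weight `lambda` on magnitude) against
#' both targets: `superior` if above both, `inferior` if below both,
#' otherwise `neither`. Equidistant decoys are reported as proximity `"tie"`.
#'
#' @param hx,hp,lx,lp,dx,dp Attribute vectors (recycled to common length).
#' @param lambda Magnitude weight in `[0, 1]`.
#' @return Data frame with columns `proximity`
#'   (`"closer-to-H"`, `"closer-to-L"`, `"tie"`) and `dominance`
#'   (`"superior"`, `"inferior"`, `"neither"`).
#' @export
classify_decoy <- function(hx, hp, lx, lp, dx, dp, lambda = 0.5) {
  if (lambda < 0 || lambda > 1) stop("classify_decoy: lambda must be in [0, 1]")
  n <- max(lengths(list(hx, hp, lx, lp, dx, dp)))
  if (any(!is.finite(dx)) || any(!is.finite(dp)))
    stop("classify_decoy: requires a ternary choice set (D attributes present)")
  dH <- sqrt((dx - hx)^2 + (dp - hp)^2)
  dL <- sqrt((dx - lx)^2 + (dp - lp)^2)
  prox <- ifelse(dH < dL, "closer-to-H", ifelse(dH > dL, "closer-to-L", "tie"))
  auH <- lambda * hx + (1 - lambda) * hp
  auL <- lambda * lx + (1 - lambda) * lp
  auD <- lambda * dx + (1 - lambda) * dp
  dom <- ifelse(auD > pmax(auH, auL), "superior",
                ifelse(auD < pmin(auH, auL), "inferior", "neither"))
  data.frame(proximity = rep_len(prox, n), dominance = rep_len(dom, n),
             stringsAsFactors = FALSE)
}

#' Write a per-condition accuracy table to CSV
#'
#' @param accuracy Output of [relative_accuracy()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(accuracy, path) {
  utils::write.csv(accuracy, path, row.names = FALSE)
  invisible(path)
}
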