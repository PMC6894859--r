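#' Validate a behavior score table
#'
#' A score table records, for each condition, replicate, reviewer and
#' worm, one label per 15-second interval over the first 90 seconds of a
#' recording: `"S"` (scrunching at least once in the interval), `"R"`
#' (a non-scrunching reaction) or `"N"` (no reaction).
#'
#' @param records data frame with columns `condition`, `replicate`,
#'   `reviewer`, `worm`, `interval` (1-6), `label`.
#' @return the validated data frame with class `score_table`.
#' @export
score_table <- function(records) {
  required <- c("condition", "replicate", "reviewer", "worm", "interval",
                "label")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0)
    stop(sprintf("score table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!all(records$interval %in% 1:6))
    stop("'interval' must be in 1..6 (15 s bins over 90 s)", call. = FALSE)
  if (!all(records$label %in% c("S", "R", "N")))
    stop("'label' must be one of \"S\", \"R\", \"N\"", call. = FALSE)
  key <- do.call(paste, c(records[c("condition", "replicate", "reviewer",
                                    "worm", "interval")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, reviewer, worm, interval) record",
         call. = FALSE)
  class(records) <- unique(c("score_table", class(records)))
  records
}

#' Aggregate scores into per-interval percentage curves
#'
#' For each replicate and interval the per-label worm counts are averaged
#' across the two reviewers and converted to percentages of worms; the
#' mean and (sample) SD across replicates give the reported curve.
#' `%reacting` counts scrunching or non-scrunching reactions (S or R), so
#' it is never below `%scrunching`.
#'
#' @param table a [score_table()].
#' @param condition condition to aggregate.
#' @return data frame of class `aggregate_curve` with columns `interval`,
#'   `pct_scrunching`, `pct_scrunching_sd`, `pct_reacting`,
#'   `pct_reacting_sd`, `n_replicates`.
#' @export
aggregate_scores <- function(table, condition) {
  stopifnot(inherits(table, "score_table"))
  sub <- table[table$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no records for condition '%s'", condition), call. = FALSE)
  reviewers <- sort(unique(sub$reviewer))
  if (length(reviewers) == 1L)
    warning("only one reviewer present; reviewer averaging degenerates")
  reps <- sort(unique(sub$replicate))
  per_rep <- array(NA_real_, dim = c(length(reps), 6L, 2L))
  for (ri in seq_along(reps)) {
    rsub <- sub[sub$replicate == reps[ri], , drop = FALSE]
    for (iv in 1:6) {
      isub <- rsub[rsub$interval == iv, , drop = FALSE]
      if (nrow(isub) == 0L)
        stop(sprintf("replicate %s is missing interval %d", reps[ri], iv),
             call. = FALSE)
      pcts <- vapply(reviewers, function(rv) {
        v <- isub[isub$reviewer == rv, , drop = FALSE]
        if (nrow(v) == 0L)
          stop(sprintf(
            "replicate %s interval %d is missing reviewer %s",
            reps[ri], iv, rv), call. = FALSE)
        c(100 * mean(v$label == "S"),
          100 * mean(v$label %in% c("S", "R")))
      }, numeric(2))
      per_rep[ri, iv, ] <- rowMeans(pcts)
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- data.frame(
    interval = 1:6,
    pct_scrunching = apply(per_rep[, , 1, drop = FALSE], 2, mean),
    pct_scrunching_sd = apply(per_rep[, , 1, drop = FALSE], 2, sd0),
    pct_reacting = apply(per_rep[, , 2, drop = FALSE], 2, mean),
    pct_reacting_sd = apply(per_rep[, , 2, drop = FALSE], 2, sd0),
    n_replicates = length(reps))
  class(out) <- c("aggregate_curve", "data.frame")
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test on the hypergeometric distribution: the p-value
#' sums the probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's (within relative
#' tolerance 1e-7). The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)` (`NaN` when 0/0). A table with any zero margin is
#' degenerate: p = 1.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio`, `p`, `degenerate`.
#' @export
fisher_exact <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) ||
      any(abs(m - round(m)) > 1e-8))
    stop("'m' must be a 2x2 matrix of non-negative integers", call. = FALSE)
  m <- round(m)
  a <- m[1, 1]; b <- m[1, 2]; c2 <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c2)  # NaN for 0/0, Inf for x/0
  r1 <- a + b; c1 <- a + c2; n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(odds_ratio = or, p = 1, degenerate = TRUE))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1), degenerate = FALSE)
}

window_to_intervals <- function(window) {
  if (is.numeric(window)) {
    if (!all(window %in% 1:6))
      stop("numeric 'window' must name intervals in 1..6", call. = FALSE)
    return(as.integer(window))
  }
  key <- gsub("\\s", "", as.character(window))
  known <- c("15-30" = 2L, "16-30" = 2L, "31-45" = 3L)
  if (!key %in% names(known))
    stop(sprintf("unknown window '%s' (use \"15-30\", \"31-45\" or interval indices)",
                 window), call. = FALSE)
  known[[key]]
}

#' Compare two conditions in an early time window with Fisher's exact test
#'
#' For each condition, each reviewer's count of outcome-positive worms in
#' the window is computed (a worm is positive if any interval of the
#' window carries the outcome label), the two reviewer counts are
#' averaged, and the average is rounded to an integer (`"half-up"` by
#' default). The resulting positive/negative counts for the two
#' conditions form the 2x2 table passed to [fisher_exact()].
#'
#' @param table a [score_table()] containing both conditions.
#' @param condition_a,condition_b the two conditions to compare.
#' @param window `"15-30"`, `"31-45"` (equivalently `"16-30"` for the
#'   former) or a vector of interval indices.
#' @param outcome `"scrunching"` (label S) or `"reacting"` (S or R).
#' @param rounding how to round reviewer-averaged counts: `"half-up"`,
#'   `"floor"` or `"ceiling"`.
#' @return object of class `window_test`: list with `counts` (2x2),
#'   `odds_ratio`, `p`, `window`, `outcome`.
#' @export
compare_windows <- function(table, condition_a, condition_b,
                            window = "15-30",
                            outcome = c("scrunching", "reacting"),
                            rounding = c("half-up", "floor", "ceiling")) {
  stopifnot(inherits(table, "score_table"))
  outcome <- match.arg(outcome)
  rounding <- match.arg(rounding)
  ivs <- window_to_intervals(window)
  labels <- if (outcome == "scrunching") "S" else c("S", "R")
  count_condition <- function(cond) {
    sub <- table[table$condition == cond & table$interval %in% ivs, ,
                 drop = FALSE]
    if (nrow(sub) == 0L)
      stop(sprintf("no records for condition '%s' in the window", cond),
           call. = FALSE)
    reviewers <- sort(unique(sub$reviewer))
    per_reviewer <- vapply(reviewers, function(rv) {
      v <- sub[sub$reviewer == rv, , drop = FALSE]
      pos <- tapply(v$label %in% labels,
                    paste(v$replicate, v$worm, sep = "\r"), any)
      c(sum(pos), length(pos))
    }, numeric(2))
    avg_pos <- mean(per_reviewer[1, ])
    n_worms <- per_reviewer[2, 1]
    if (!all(per_reviewer[2, ] == n_worms))
      stop(sprintf("reviewers scored different worm sets in '%s'", cond),
           call. = FALSE)
    pos <- switch(rounding,
                  "half-up" = round_half_up(avg_pos, 0),
                  floor = floor(avg_pos),
                  ceiling = ceiling(avg_pos))
    c(pos = pos, neg = n_worms - pos)
  }
  ca <- count_condition(condition_a)
  cb <- count_condition(condition_b)
  counts <- rbind(ca, cb)
  dimnames(counts) <- list(c(condition_a, condition_b),
                           c(outcome, paste0("not_", outcome)))
  ft <- fisher_exact(counts)
  structure(list(counts = counts, odds_ratio = ft$odds_ratio, p = ft$p,
                 degenerate = ft$degenerate, window = window,
                 outcome = outcome),
            class = "window_test")
}

#' @export
print.window_test <- function(x, ...) {
  cat(sprintf("<window_test> %s in window %s: OR = %.3g, p = %.4g%s\n",
              x$outcome, paste(x$window, collapse = ","), x$odds_ratio,
              x$p, if (x$degenerate) " (degenerate margins)" else ""))
  print(x$counts)
  invisible(x)
}

#' Scrunching latency from an aggregate curve
#'
#' First 15-second interval at which the mean percentage of scrunching
#' worms reaches a threshold.
#'
#' @param curve an [aggregate_scores()] result.
#' @param threshold_pct threshold in (0, 100].
#' @return 1-based interval index, or `NA_integer_` if never reached.
#' @export
latency_summary <- function(curve, threshold_pct = 50) {
  stopifnot(inherits(curve, "aggregate_curve"))
  if (threshold_pct <= 0 || threshold_pct > 100)
    stop("'threshold_pct' must lie in (0, 100]", call. = FALSE)
  hit <- which(curve$pct_scrunching >= threshold_pct)
  if (length(hit) == 0L) NA_integer_ else curve$interval[hit[1]]
}
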