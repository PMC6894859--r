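#' Smooth a length trace with a centered moving average
#'
#' Boxcar smoothing with truncated windows at the trace edges; the trace
#' length is unchanged.
#'
#' @param trace a [length_trace()].
#' @param window_s window width in seconds; must be at least `2/fps`.
#' @return the smoothed [length_trace()].
#' @export
smooth_trace <- function(trace, window_s = 0.3) {
  stopifnot(inherits(trace, "length_trace"))
  if (window_s < 2 / trace$fps)
    stop("'window_s' must be at least 2/fps", call. = FALSE)
  k <- round(window_s * trace$fps)
  if (k %% 2 == 0) k <- k + 1L
  out <- trace
  out$lengths <- moving_average(trace$lengths, k)
  out
}

# Strict local extrema of y after collapsing runs of equal values; the run
# midpoint represents a plateau. Endpoints count as extrema (their type is
# set by the first/last monotone segment). Returns idx/type/value, with
# type +1 = peak, -1 = trough, guaranteed alternating.
find_extrema <- function(y) {
  n <- length(y)
  first_of_run <- which(c(TRUE, diff(y) != 0))
  run_end <- c(first_of_run[-1] - 1L, n)
  rep_idx <- (first_of_run + run_end) %/% 2L
  z <- y[first_of_run]
  m <- length(z)
  if (m < 2L) return(data.frame(idx = integer(0), type = integer(0),
                                value = numeric(0)))
  type <- integer(m)
  type[1] <- if (z[1] > z[2]) 1L else -1L
  type[m] <- if (z[m] > z[m - 1]) 1L else -1L
  if (m > 2L) {
    mid <- 2:(m - 1)
    up <- z[mid] > z[mid - 1] & z[mid] > z[mid + 1]
    dn <- z[mid] < z[mid - 1] & z[mid] < z[mid + 1]
    type[mid] <- ifelse(up, 1L, ifelse(dn, -1L, 0L))
  }
  keep <- type != 0L
  ex <- data.frame(idx = rep_idx[keep], type = type[keep], value = z[keep])
  enforce_alternation(ex)
}

# Merge consecutive same-type extrema, keeping the more extreme one.
enforce_alternation <- function(ex) {
  repeat {
    if (nrow(ex) < 2L) return(ex)
    same <- which(diff(ex$type) == 0L)
    if (length(same) == 0L) return(ex)
    i <- same[1]
    drop <- if (ex$type[i] == 1L) {
      if (ex$value[i] >= ex$value[i + 1]) i + 1L else i
    } else {
      if (ex$value[i] <= ex$value[i + 1]) i + 1L else i
    }
    ex <- ex[-drop, , drop = FALSE]
  }
}

# Zigzag pruning: repeatedly delete the adjacent extrema pair with the
# smallest amplitude below `thr`, re-enforcing alternation.
prune_by_prominence <- function(ex, thr) {
  repeat {
    if (nrow(ex) < 2L) return(ex)
    amp <- abs(diff(ex$value))
    j <- which.min(amp)
    if (amp[j] >= thr) return(ex)
    ex <- ex[-c(j, j + 1L), , drop = FALSE]
    ex <- enforce_alternation(ex)
  }
}

# Enforce a minimum spacing between consecutive peaks: drop the lower of
# two too-close peaks together with the shallower bounding trough.
enforce_min_period <- function(ex, min_gap_idx) {
  repeat {
    pk <- which(ex$type == 1L)
    if (length(pk) < 2L) return(ex)
    gaps <- diff(ex$idx[pk])
    bad <- which(gaps < min_gap_idx)
    if (length(bad) == 0L) return(ex)
    i1 <- pk[bad[1]]; i2 <- pk[bad[1] + 1L]
    drop_pk <- if (ex$value[i1] >= ex$value[i2]) i2 else i1
    ex <- ex[-drop_pk, , drop = FALSE]
    ex <- enforce_alternation(ex)
  }
}

# Two-sided ("kinked") parabola refinement of an extremum near index i:
# y is modelled as v - cL (t - tp)^2 left of the apex and v - cR (t - tp)^2
# right of it (sign flipped for troughs), with the apex position tp scanned
# over a sub-sample grid and (v, cL, cR) solved by least squares at each
# candidate. A plain 3-point quadratic vertex is biased toward the
# flatter side when the curvature differs across the extremum — exactly
# the situation in an asymmetric gait, where elongation is slower than
# contraction — while the kinked model is unbiased there.
# Returns c(offset_in_samples, refined_value).
refine_extremum_kink <- function(y, i, type, halfwin = 2L) {
  n <- length(y)
  if (i - halfwin < 1L || i + halfwin > n) return(refine_extremum(y, i))
  idx <- (i - halfwin):(i + halfwin)
  tt <- idx - i
  z <- type * y[idx]              # fit a peak model on type-flipped data
  best_rss <- Inf
  best <- NULL
  for (tp in seq(-0.75, 0.75, by = 0.05)) {
    d <- tt - tp
    x2 <- -(d^2) * (d < 0)
    x3 <- -(d^2) * (d >= 0)
    xtx <- crossprod(cbind(1, x2, x3))
    if (abs(det(xtx)) < 1e-10) next
    beta <- solve(xtx, crossprod(cbind(1, x2, x3), z))
    if (beta[2] < 0 || beta[3] < 0) next   # curvatures must open downward
    fitted <- beta[1] + beta[2] * x2 + beta[3] * x3
    rss <- sum((z - fitted)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c(tp, type * beta[1])
    }
  }
  if (is.null(best)) return(refine_extremum(y, i))
  best
}

# 3-point quadratic refinement of an extremum at index i of y; returns
# c(offset_in_samples, refined_value). Falls back to the sample itself
# when the curvature is degenerate or the vertex leaves the sample cell.
refine_extremum <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(c(0, y[i]))
  a <- y[i - 1]; b <- y[i]; c2 <- y[i + 1]
  denom <- a - 2 * b + c2
  if (!is.finite(denom) || abs(denom) < 1e-12) return(c(0, b))
  delta <- 0.5 * (a - c2) / denom
  if (abs(delta) > 0.5) return(c(0, b))
  val <- b - 0.25 * (a - c2) * delta
  c(delta, val)
}

#' Detect oscillation cycles in a length trace
#'
#' Finds alternating trough/peak extrema whose amplitude is at least
#' `prominence_frac` of the median trace length and whose peak-to-peak
#' spacing is at least `min_period_s`, then assembles trough-peak-trough
#' cycles. Peak/trough times and values are refined with a 3-point
#' quadratic fit evaluated on the raw trace (`raw`, defaulting to the
#' input), so detection can run on a smoothed trace without biasing the
#' amplitude readout.
#'
#' @param trace a [length_trace()], typically smoothed
#'   (see [smooth_trace()]).
#' @param prominence_frac minimum extremum-to-extremum amplitude as a
#'   fraction of the median length, in (0, 1).
#' @param min_period_s minimum spacing between consecutive peaks, seconds.
#' @param raw optional unsmoothed [length_trace()] used for the quadratic
#'   refinement of extremum values and times.
#' @return data frame of class `gait_cycles` with one row per cycle:
#'   `t_start`, `t_peak`, `t_end` (seconds), `L_peak`, `L_trough_low`
#'   (the lower of the two bounding troughs). May have zero rows.
#' @export
detect_cycles <- function(trace, prominence_frac = 0.10,
                          min_period_s = 0.5, raw = NULL) {
  stopifnot(inherits(trace, "length_trace"))
  check_fraction(prominence_frac, "prominence_frac")
  y <- trace$lengths
  ex <- find_extrema(y)
  empty <- data.frame(t_start = numeric(0), t_peak = numeric(0),
                      t_end = numeric(0), L_peak = numeric(0),
                      L_trough_low = numeric(0))
  class(empty) <- c("gait_cycles", "data.frame")
  if (nrow(ex) < 3L) return(empty)
  ex <- prune_by_prominence(ex, prominence_frac * stats::median(y))
  ex <- enforce_min_period(ex, min_period_s * trace$fps)
  if (nrow(ex) < 3L) return(empty)
  yr <- if (is.null(raw)) y else raw$lengths
  if (length(yr) != length(y))
    stop("'raw' must have the same length as 'trace'", call. = FALSE)
  # Refinement window scales with the cycle length: slow gaits have long,
  # shallow phases where a wider fit averages more noise, while fast gaits
  # need a short window that stays inside the contraction phase.
  pk_idx <- ex$idx[ex$type == 1L]
  spacing <- if (length(pk_idx) >= 2L) stats::median(diff(pk_idx))
             else min_period_s * trace$fps
  halfwin <- max(2L, min(6L, as.integer(round(0.18 * spacing))))
  ref <- t(mapply(function(i, ty) refine_extremum_kink(yr, i, ty, halfwin),
                  ex$idx, ex$type))
  ex$t <- (ex$idx - 1 + ref[, 1]) / trace$fps
  ex$v <- ref[, 2]
  pk <- which(ex$type == 1L)
  pk <- pk[pk > 1L & pk < nrow(ex)]
  if (length(pk) == 0L) return(empty)
  cycles <- data.frame(
    t_start = ex$t[pk - 1L], t_peak = ex$t[pk], t_end = ex$t[pk + 1L],
    L_peak = ex$v[pk],
    L_trough_low = pmin(ex$v[pk - 1L], ex$v[pk + 1L]))
  class(cycles) <- c("gait_cycles", "data.frame")
  cycles
}

#' Select the earliest analysable run of cycles
#'
#' Returns the earliest run of at least `min_cycles` consecutive cycles
#' (adjacent cycles share a trough) none of which overlaps a bend-flagged
#' span of the trace. With fewer qualifying cycles an
#' `insufficient_oscillation` result is returned, which drives a gliding
#' call in the classifier.
#'
#' @param cycles a `gait_cycles` data frame from [detect_cycles()].
#' @param min_cycles minimum number of consecutive cycles.
#' @param bend_spans optional data frame with columns `t0`, `t1` (seconds)
#'   of bent-worm spans to avoid, e.g. from [bend_spans()].
#' @param gap_tol_s tolerance when testing whether two cycles are
#'   consecutive.
#' @return list with `window = c(t0, t1)` and `cycles` (the selected
#'   subset), or an object of class `insufficient_oscillation`.
#' @export
select_window <- function(cycles, min_cycles = 4, bend_spans = NULL,
                          gap_tol_s = 0.2) {
  n <- nrow(cycles)
  insufficient <- structure(
    list(reason = "fewer than min_cycles consecutive clean cycles",
         n_cycles = n, min_cycles = min_cycles),
    class = "insufficient_oscillation")
  if (n < min_cycles) return(insufficient)
  clean <- rep(TRUE, n)
  if (!is.null(bend_spans) && nrow(bend_spans) > 0) {
    for (i in seq_len(n)) {
      overlap <- bend_spans$t0 < cycles$t_end[i] &
        bend_spans$t1 > cycles$t_start[i]
      if (any(overlap)) clean[i] <- FALSE
    }
  }
  consec <- c(FALSE,
              abs(cycles$t_start[-1] - cycles$t_end[-n]) <= gap_tol_s)
  # run ids: break at non-consecutive or non-clean cycles
  run <- cumsum(!(consec & clean & c(FALSE, clean[-n])))
  for (r in unique(run)) {
    members <- which(run == r & clean)
    if (length(members) >= min_cycles) {
      sel <- cycles[members, , drop = FALSE]
      return(list(window = c(sel$t_start[1], sel$t_end[nrow(sel)]),
                  cycles = sel))
    }
  }
  insufficient
}

#' Bent-worm time spans of a trace
#'
#' Collapses the per-frame bend flags of a trace into time intervals.
#'
#' @param trace a [length_trace()].
#' @return data frame with columns `t0`, `t1`; zero rows when no frame is
#'   flagged.
#' @export
bend_spans <- function(trace) {
  f <- trace$bend_flag
  if (!any(f)) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t0 = trace$times[starts[keep]], t1 = trace$times[ends[keep]])
}

#' Summarize cycles into the four gait parameters
#'
#' Computes, over the selected cycles: frequency = number of cycles over
#' the trough-to-trough span; maximum elongation = per-cycle
#' (peak - lower trough)/peak averaged over cycles; asymmetry = summed
#' elongation (trough-to-peak) time over summed cycle time; and relative
#' speed = frequency x maximum elongation (an exact identity).
#'
#' @param trace the [length_trace()] the cycles came from.
#' @param cycles a `gait_cycles` data frame (typically the `cycles`
#'   element from [select_window()]).
#' @return object of class `gait_summary`: list with `frequency`,
#'   `max_elongation`, `speed`, `asymmetry`, `n_cycles`, `window`, `id`.
#' @export
summarize_gait <- function(trace, cycles) {
  if (inherits(cycles, "insufficient_oscillation"))
    stop("cannot summarize an insufficient-oscillation result",
         call. = FALSE)
  n <- nrow(cycles)
  if (n == 0L) stop("empty cycle set", call. = FALSE)
  span <- cycles$t_end[n] - cycles$t_start[1]
  frequency <- n / span
  max_elongation <- mean((cycles$L_peak - cycles$L_trough_low) /
                           cycles$L_peak)
  asymmetry <- sum(cycles$t_peak - cycles$t_start) /
    sum(cycles$t_end - cycles$t_start)
  structure(
    list(frequency = frequency, max_elongation = max_elongation,
         speed = frequency * max_elongation, asymmetry = asymmetry,
         n_cycles = n, window = c(cycles$t_start[1], cycles$t_end[n]),
         id = trace$id),
    class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<gait_summary '%s'> %d cycles in [%.1f, %.1f] s\n",
    "  frequency %.3f Hz, max elongation %.3f, speed %.3f BL/s,",
    " asymmetry %.3f\n"),
    x$id, x$n_cycles, x$window[1], x$window[2],
    x$frequency, x$max_elongation, x$speed, x$asymmetry))
  invisible(x)
}

#' Quantify a trace end to end
#'
#' Convenience wrapper: smooth, detect cycles (refining on the raw trace),
#' select the earliest clean run of at least `min_cycles` cycles, and
#' summarize. Returns an `insufficient_oscillation` object when no
#' qualifying run exists (e.g. for gliding).
#'
#' @param trace a [length_trace()].
#' @param smooth_window_s,prominence_frac,min_period_s,min_cycles tuning
#'   parameters, see [smooth_trace()], [detect_cycles()],
#'   [select_window()].
#' @return a [summarize_gait()] result or an `insufficient_oscillation`
#'   object.
#' @export
quantify_trace <- function(trace, smooth_window_s = 0.3,
                           prominence_frac = 0.10, min_period_s = 0.5,
                           min_cycles = 4) {
  sm <- smooth_trace(trace, smooth_window_s)
  cycles <- detect_cycles(sm, prominence_frac = prominence_frac,
                          min_period_s = min_period_s, raw = trace)
  sel <- select_window(cycles, min_cycles = min_cycles,
                       bend_spans = bend_spans(trace))
  if (inherits(sel, "insufficient_oscillation")) return(sel)
  summarize_gait(trace, sel$cycles)
}

#' Count scrunches after the initial contraction
#'
#' Counts detected cycles, discarding any cycle whose peak falls before
#' the end of the initial monotone contraction from t = 0 (amputation
#' recordings start with an immediate contraction that is not a scrunch).
#'
#' @param trace a [length_trace()].
#' @param smooth_window_s,prominence_frac,min_period_s see
#'   [quantify_trace()].
#' @return integer scrunch count (0 for a constant or purely contracting
#'   trace).
#' @export
count_scrunches <- function(trace, smooth_window_s = 0.3,
                            prominence_frac = 0.10, min_period_s = 0.5) {
  sm <- smooth_trace(trace, smooth_window_s)
  cycles <- detect_cycles(sm, prominence_frac = prominence_frac,
                          min_period_s = min_period_s, raw = trace)
  if (nrow(cycles) == 0L) return(0L)
  y <- sm$lengths
  tol <- 0.25 * prominence_frac * stats::median(y)
  running_min <- cummin(y)
  rising <- which(y > running_min + tol)
  contraction_end_t <- if (length(rising) == 0L) max(sm$times) else {
    i <- rising[1]
    sm$times[which.min(y[1:i])]
  }
  sum(cycles$t_peak > contraction_end_t)
}

#' Population summary across worms
#'
#' Mean, SD and N per gait parameter across a set of per-worm summaries.
#' The population speed is the mean of the per-worm speeds (not the
#' product of the mean frequency and mean elongation). With a single worm
#' the SD is reported as 0 and flagged.
#'
#' @param summaries list of [summarize_gait()] results.
#' @return data frame with columns `parameter`, `mean`, `sd`, `n`,
#'   `sd_defined`.
#' @export
batch_summarize <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries given", call. = FALSE)
  if (inherits(summaries, "gait_summary")) summaries <- list(summaries)
  pars <- c("frequency", "max_elongation", "speed", "asymmetry")
  vals <- vapply(summaries, function(s) unlist(s[pars]), numeric(4))
  vals <- matrix(vals, nrow = 4,
                 dimnames = list(pars, NULL))
  n <- ncol(vals)
  data.frame(parameter = pars,
             mean = rowMeans(vals),
             sd = if (n > 1) apply(vals, 1, stats::sd) else rep(0, 4),
             n = n,
             sd_defined = n > 1,
             row.names = NULL)
}
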