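#' @keywords internal
"_PACKAGE"

# Round half away from zero (half-up for non-negative values), as used for
# reporting gait parameters at 2 decimals. Base round() is half-to-even.
#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when reporting gait parameters (e.g. speeds to 2 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE,
                                   nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  stop_if_not_scalar_num(x, name)
  if (x <= 0 || x >= 1)
    stop(sprintf("'%s' must lie strictly in (0, 1) (got %g)", name, x),
         call. = FALSE)
  invisible(x)
}

# Centered moving average with truncated windows at the edges; k odd.
moving_average <- function(y, k) {
  n <- length(y)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
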