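# Independent oracles and fixture builders used across the test files.

# Filled digitized ellipse mask with semi-axes (a, b), optionally rotated
# by 90 degrees (swap axes).
ellipse_mask <- function(a, b, pad = 3) {
  h <- 2 * a + 2 * pad + 1
  w <- 2 * b + 2 * pad + 1
  cx <- (h + 1) / 2
  cy <- (w + 1) / 2
  outer(seq_len(h), seq_len(w),
        function(i, j) ((i - cx) / a)^2 + ((j - cy) / b)^2 <= 1)
}

rect_mask <- function(len, wid, pad = 3) {
  m <- matrix(FALSE, len + 2 * pad, wid + 2 * pad)
  m[pad + seq_len(len), pad + seq_len(wid)] <- TRUE
  m
}

# Brute-force equivalent-ellipse major axis: explicit second-moment sums
# over enumerated pixel coordinates and the closed-form eigenvalues of the
# 2x2 covariance matrix (independent of the package implementation).
brute_force_major_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  mx <- sum(idx[, 1]) / n
  my <- sum(idx[, 2]) / n
  sxx <- sum((idx[, 1] - mx)^2) / n
  syy <- sum((idx[, 2] - my)^2) / n
  sxy <- sum((idx[, 1] - mx) * (idx[, 2] - my)) / n
  lam_max <- (sxx + syy) / 2 + sqrt(((sxx - syy) / 2)^2 + sxy^2)
  4 * sqrt(lam_max)
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# p-value, written from the choose() definition.
fisher_enumeration <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c2 <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c2; n <- a + b + c2 + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  p_obs <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Two-sided t-distribution tail probability via direct numerical
# quadrature of the t density (independent of stats::pt).
t_p_quadrature <- function(t, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# Random label-probability vector (S, R, N) derived from a seed.
with_seed_vec <- function(seed) {
  set.seed(seed)
  p <- stats::runif(3)
  p / sum(p)
}

# The published parameter regimes used as simulation ground truth.
non_peristalsis_regimes <- function() {
  tab <- published_gait_table()
  tab[tab$stimulus != "peristalsis", , drop = FALSE]
}

# A gait_summary built directly from tabulated parameter values.
summary_from_row <- function(frequency, max_elongation, asymmetry,
                             speed = frequency * max_elongation,
                             id = "tabulated") {
  structure(list(frequency = frequency, max_elongation = max_elongation,
                 speed = speed, asymmetry = asymmetry, n_cycles = NA_integer_,
                 window = c(NA_real_, NA_real_), id = id),
            class = "gait_summary")
}
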