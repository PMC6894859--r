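#' Gait simulation parameters
#'
#' Parameter set for the synthetic locomotion generator. Three gaits are
#' supported: gliding (constant body length), peristalsis (low-amplitude,
#' near-symmetric oscillation) and scrunching (large-amplitude oscillation
#' with a longer elongation than contraction phase). The oscillation is a
#' cosine-eased ramp between trough and peak, so the trace is periodic and
#' piecewise smooth: differentiable peaks make peak detection behave as it
#' does on real recordings without changing the ground truth.
#'
#' @param gait_kind one of `"gliding"`, `"peristalsis"`, `"scrunching"`.
#' @param frequency_hz oscillation frequency in cycles per second
#'   (ignored for gliding).
#' @param max_elongation per-cycle (peak - trough)/peak, in (0, 1)
#'   (ignored for gliding).
#' @param asymmetry fraction of each cycle spent elongating, in (0, 1);
#'   values above 0.5 are the scrunching hallmark.
#' @param gliding_length body length during gliding, in pixels.
#' @param peak_factor peak length as a multiple of the gliding length.
#' @param noise_sd additive Gaussian noise SD as a fraction of the gliding
#'   length, i.i.d. per frame, added after waveform construction.
#' @param duration_s recording duration in seconds.
#' @param fps frame rate in frames per second.
#' @param gliding_lead_s seconds of gliding before oscillation onset.
#' @param seed RNG seed making the trace reproducible.
#'
#' @return an object of class `gait_params`.
#' @seealso [gait_preset()], [generate_length_trace()]
#' @export
gait_params <- function(gait_kind = c("scrunching", "peristalsis", "gliding"),
                        frequency_hz = 0.72, max_elongation = 0.52,
                        asymmetry = 0.59, gliding_length = 100,
                        peak_factor = 1.2, noise_sd = 0,
                        duration_s = 30, fps = 10,
                        gliding_lead_s = 0, seed = 1L) {
  gait_kind <- match.arg(gait_kind)
  stop_if_not_scalar_num(gliding_length, "gliding_length", positive = TRUE)
  stop_if_not_scalar_num(peak_factor, "peak_factor", positive = TRUE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  stop_if_not_scalar_num(duration_s, "duration_s", positive = TRUE)
  stop_if_not_scalar_num(fps, "fps", positive = TRUE)
  stop_if_not_scalar_num(gliding_lead_s, "gliding_lead_s", nonneg = TRUE)
  if (gait_kind != "gliding") {
    stop_if_not_scalar_num(frequency_hz, "frequency_hz", positive = TRUE)
    check_fraction(max_elongation, "max_elongation")
    check_fraction(asymmetry, "asymmetry")
    if (peak_factor * (1 - max_elongation) <= 0)
      stop("trough length peak_factor*(1-max_elongation) must be > 0",
           call. = FALSE)
    if (gliding_lead_s >= duration_s)
      stop("'gliding_lead_s' must be shorter than 'duration_s'",
           call. = FALSE)
  }
  structure(
    list(gait_kind = gait_kind, frequency_hz = frequency_hz,
         max_elongation = max_elongation, asymmetry = asymmetry,
         gliding_length = gliding_length, peak_factor = peak_factor,
         noise_sd = noise_sd, duration_s = duration_s, fps = fps,
         gliding_lead_s = gliding_lead_s, seed = as.integer(seed)),
    class = "gait_params")
}

#' Preset gait parameter regimes
#'
#' Convenience constructors for the three gaits with species-typical
#' parameter values (D. japonica scrunching: f = 0.72 Hz, A = 0.52,
#' a = 0.59; S. mediterranea scrunching: f = 0.40, A = 0.44, a = 0.62;
#' peristalsis: f = 0.26, A = 0.23, a = 0.50).
#'
#' @param name preset name.
#' @param ... overrides passed on to [gait_params()].
#' @return a `gait_params` object.
#' @export
gait_preset <- function(name = c("scrunching_dj", "scrunching_sm",
                                 "peristalsis", "gliding"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    scrunching_dj = list(gait_kind = "scrunching", frequency_hz = 0.72,
                         max_elongation = 0.52, asymmetry = 0.59),
    scrunching_sm = list(gait_kind = "scrunching", frequency_hz = 0.40,
                         max_elongation = 0.44, asymmetry = 0.62),
    peristalsis = list(gait_kind = "peristalsis", frequency_hz = 0.26,
                       max_elongation = 0.23, asymmetry = 0.50),
    gliding = list(gait_kind = "gliding"))
  do.call(gait_params, utils::modifyList(base, list(...)))
}

# Deterministic noise-free waveform evaluated at times t (seconds).
waveform_length <- function(params, t) {
  p <- params
  if (p$gait_kind == "gliding")
    return(rep(p$gliding_length, length(t)))
  l_peak <- p$peak_factor * p$gliding_length
  l_trough <- l_peak * (1 - p$max_elongation)
  period <- 1 / p$frequency_hz
  out <- rep(p$gliding_length, length(t))
  tt <- t - p$gliding_lead_s
  osc <- tt >= 0
  tau <- tt[osc] %% period
  x <- numeric(sum(osc))
  elong <- tau <= p$asymmetry * period
  x[elong] <- tau[elong] / (p$asymmetry * period)
  x[!elong] <- 1 - (tau[!elong] - p$asymmetry * period) /
    ((1 - p$asymmetry) * period)
  out[osc] <- l_trough + (l_peak - l_trough) * 0.5 * (1 - cos(pi * x))
  out
}

#' Generate a synthetic body-length trace with ground truth
#'
#' Emits `floor(duration_s * fps) + 1` samples at `t = 0, 1/fps, ...`.
#' Oscillatory gaits ramp between trough and peak with a cosine easing;
#' the elongation phase occupies `asymmetry` of each cycle. Additive
#' Gaussian noise (SD `noise_sd * gliding_length`) is applied after the
#' waveform is built; noisy lengths are clipped to stay strictly positive.
#'
#' @param params a [gait_params()] object.
#' @return a list with elements `trace` (a [length_trace()], raw pixels)
#'   and `truth` (class `ground_truth`: the parameters, per-frame true
#'   lengths, oscillation trough times, and the exact parameter values
#'   `frequency`, `max_elongation`, `speed = frequency * max_elongation`
#'   and `asymmetry`).
#' @export
generate_length_trace <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  n <- floor(p$duration_s * p$fps) + 1L
  t <- (seq_len(n) - 1) / p$fps
  true_len <- waveform_length(p, t)
  lengths <- true_len
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, stats::rnorm(n, 0, p$noise_sd * p$gliding_length))
    lengths <- pmax(lengths + noise, 1e-6 * p$gliding_length)
  }
  trough_times <- numeric(0)
  if (p$gait_kind != "gliding") {
    period <- 1 / p$frequency_hz
    k_max <- floor((p$duration_s - p$gliding_lead_s) / period + 1e-9)
    trough_times <- p$gliding_lead_s + (0:k_max) * period
  }
  truth <- structure(
    list(params = p,
         times = t,
         true_length_px = true_len,
         trough_times_s = trough_times,
         frequency = if (p$gait_kind == "gliding") 0 else p$frequency_hz,
         max_elongation = if (p$gait_kind == "gliding") 0 else p$max_elongation,
         speed = if (p$gait_kind == "gliding") 0 else
           p$frequency_hz * p$max_elongation,
         asymmetry = if (p$gait_kind == "gliding") NA_real_ else p$asymmetry,
         masks = NULL),
    class = "ground_truth")
  list(trace = length_trace(lengths, p$fps,
                            id = sprintf("sim_%s_seed%d", p$gait_kind, p$seed)),
       truth = truth)
}

#' Simulate a reviewer-scored behavior table
#'
#' Emulates two blind reviewers scoring each worm in six 15-second
#' intervals as scrunching (`"S"`), exhibiting a non-scrunching reaction
#' (`"R"`) or not reacting (`"N"`). The second reviewer repeats the first
#' reviewer's label with probability `agreement` and otherwise re-draws
#' from the interval's label distribution.
#'
#' @param n_worms worms per replicate.
#' @param n_replicates experimental replicates.
#' @param interval_probs either a length-3 probability vector (S, R, N),
#'   recycled over the 6 intervals, or a 6 x 3 matrix with one row per
#'   interval. Each row must sum to 1.
#' @param agreement probability in `[0, 1]` that reviewer 2 copies
#'   reviewer 1's label.
#' @param condition condition label stored in the table.
#' @param seed RNG seed.
#' @return a `score_table` data frame with columns `condition`,
#'   `replicate`, `reviewer`, `worm`, `interval`, `label`.
#' @export
generate_score_table <- function(n_worms, n_replicates, interval_probs,
                                 agreement = 0.9, condition = "condition",
                                 seed = 1L) {
  if (is.null(dim(interval_probs)))
    interval_probs <- matrix(interval_probs, nrow = 6, ncol = 3, byrow = TRUE)
  interval_probs <- as.matrix(interval_probs)
  if (!all(dim(interval_probs) == c(6L, 3L)))
    stop("'interval_probs' must be a length-3 vector or a 6 x 3 matrix",
         call. = FALSE)
  if (any(interval_probs < 0) ||
      any(abs(rowSums(interval_probs) - 1) > 1e-8))
    stop("each interval's label probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (agreement < 0 || agreement > 1)
    stop("'agreement' must lie in [0, 1]", call. = FALSE)
  labels <- c("S", "R", "N")
  recs <- with_seed(seed, {
    out <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      l1 <- l2 <- matrix("", n_worms, 6L)
      for (iv in 1:6) {
        l1[, iv] <- sample(labels, n_worms, TRUE, prob = interval_probs[iv, ])
        copy <- stats::runif(n_worms) < agreement
        redraw <- sample(labels, n_worms, TRUE, prob = interval_probs[iv, ])
        l2[, iv] <- ifelse(copy, l1[, iv], redraw)
      }
      out[[r]] <- data.frame(
        condition = condition, replicate = r,
        reviewer = rep(1:2, each = n_worms * 6L),
        worm = rep(rep(seq_len(n_worms), times = 6L), 2L),
        interval = rep(rep(1:6, each = n_worms), 2L),
        label = c(as.vector(l1), as.vector(l2)))
    }
    do.call(rbind, out)
  })
  score_table(recs)
}

#' Packaged published gait parameter table
#'
#' Per-species, per-stimulus gait parameters (mean and SD of frequency,
#' maximum elongation, speed and fraction of time spent elongating, plus
#' the assigned gait label and sample size) for the eleven characterized
#' conditions, including the amputation and peristalsis reference rows.
#'
#' @return data frame with one row per condition.
#' @export
published_gait_table <- function() {
  path <- system.file("extdata", "published_gait_parameters.csv",
                      package = "scrunchr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
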