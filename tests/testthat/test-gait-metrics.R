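sim_scrunch <- function(f = 0.5, A = 0.5, a = 0.6, duration = 10, fps = 10,
                        noise = 0, seed = 1L, lead = 0) {
  generate_length_trace(gait_params(
    "scrunching", frequency_hz = f, max_elongation = A, asymmetry = a,
    duration_s = duration, fps = fps, noise_sd = noise,
    gliding_lead_s = lead, seed = seed))
}

test_that("smoothing preserves constants and reduces noise variance", {
  const <- length_trace(rep(5, 40), fps = 10)
  expect_identical(smooth_trace(const, 0.5)$lengths, const$lengths)

  set.seed(4)
  noisy <- length_trace(100 + stats::rnorm(400), fps = 10)
  expect_lt(stats::var(smooth_trace(noisy, 0.5)$lengths),
            stats::var(noisy$lengths))
  expect_error(smooth_trace(const, 0.1), "2/fps")
})

test_that("boxcar attenuation of a sinusoid matches the analytic response", {
  fps <- 100; f0 <- 0.5; win <- 0.3
  tr <- length_trace(10 + sin(2 * pi * f0 * (0:2000) / fps), fps = fps)
  sm <- smooth_trace(tr, win)
  core <- 300:1700  # avoid edge-truncated windows
  amp <- (max(sm$lengths[core]) - min(sm$lengths[core])) / 2
  k <- round(win * fps) + 1  # implementation rounds to an odd width
  gain <- abs(sum(cos(2 * pi * f0 * (seq_len(k) - (k + 1) / 2) / fps))) / k
  expect_lt(abs(amp - gain) / gain, 0.02)
})

test_that("cycle detection counts and places noise-free cycles exactly", {
  expect_identical(nrow(detect_cycles(length_trace(rep(7, 100), 10))), 0L)

  sim <- sim_scrunch()
  cy <- detect_cycles(smooth_trace(sim$trace, 0.3), raw = sim$trace)
  expect_identical(nrow(cy), 5L)
  truth_troughs <- sim$truth$trough_times_s
  expect_lt(max(abs(cy$t_start - truth_troughs[1:5])), 0.1 + 1e-6)
  expect_lt(max(abs(cy$t_end - truth_troughs[2:6])), 0.1 + 1e-6)
  expect_true(all(cy$t_start < cy$t_peak & cy$t_peak < cy$t_end))
})

test_that("cycle counts match ground truth on noisy traces", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_scrunch(noise = 0.02, seed = s)
    cy <- detect_cycles(smooth_trace(sim$trace, 0.3), raw = sim$trace)
    nrow(cy) == 5L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("window selection returns the earliest clean run", {
  sim <- sim_scrunch(duration = 12)
  cy <- detect_cycles(smooth_trace(sim$trace, 0.3), raw = sim$trace)
  sel <- select_window(cy)
  expect_identical(nrow(sel$cycles), nrow(cy))
  expect_equal(sel$window[1], cy$t_start[1])

  few <- cy[1:3, ]
  expect_s3_class(select_window(few), "insufficient_oscillation")

  # two clean cycles, a bend-flagged gap, then five clean ones
  spans <- data.frame(t0 = cy$t_start[3] + 0.2, t1 = cy$t_start[3] + 0.4)
  sim2 <- sim_scrunch(duration = 16)
  cy2 <- detect_cycles(smooth_trace(sim2$trace, 0.3), raw = sim2$trace)
  sel2 <- select_window(cy2, min_cycles = 4, bend_spans = spans)
  expect_identical(nrow(sel2$cycles), nrow(cy2) - 3L)
  expect_gt(sel2$window[1], spans$t1)
})

test_that("summary formulas follow their definitions", {
  cycles <- data.frame(t_start = c(0, 2), t_peak = c(1.2, 3.2),
                       t_end = c(2, 4), L_peak = c(2, 2),
                       L_trough_low = c(1, 1))
  class(cycles) <- c("gait_cycles", "data.frame")
  tr <- length_trace(rep(1.5, 41), 10)
  s <- summarize_gait(tr, cycles)
  expect_equal(s$frequency, 2 / 4)
  expect_equal(s$max_elongation, 0.5)
  expect_equal(s$asymmetry, 2.4 / 4)
  expect_identical(s$speed, s$frequency * s$max_elongation)
  expect_error(summarize_gait(tr, cycles[0, ]), "empty")
})

test_that("the tabulated AITC parameters give the printed speed", {
  s <- summary_from_row(0.72, 0.52, 0.59)
  expect_identical(round_half_up(s$speed, 2), 0.37)
})

test_that("a symmetric triangle wave has asymmetry one half", {
  y <- 100 + 20 * abs(((0:400) / 20) %% 2 - 1)  # period 4 s at 10 fps
  tr <- length_trace(y, 10)
  cy <- detect_cycles(smooth_trace(tr, 0.3), raw = tr)
  s <- summarize_gait(tr, cy)
  expect_lt(abs(s$asymmetry - 0.5), 0.1 / 4 + 1e-6)  # one frame-quantum
})

test_that("speed equals frequency times elongation for every summary", {
  for (seed in 1:5) {
    sim <- sim_scrunch(f = 0.4 + 0.1 * seed, noise = 0.02, seed = seed,
                       duration = 20)
    q <- quantify_trace(sim$trace)
    expect_identical(q$speed, q$frequency * q$max_elongation)
  }
})

test_that("parameters recover the generator truth at the published regimes", {
  tab <- non_peristalsis_regimes()
  rows <- tab[tab$stimulus %in% c("AITC", "anandamide"), ]
  for (r in seq_len(nrow(rows))) {
    q <- quantify_trace(sim_scrunch(rows$frequency_mean[r],
                                    rows$max_elongation_mean[r],
                                    rows$asymmetry_mean[r],
                                    duration = 30, noise = 0.01,
                                    seed = 100 + r)$trace)
    expect_lt(abs(q$frequency - rows$frequency_mean[r]) /
                rows$frequency_mean[r], 0.05)
    expect_lt(abs(q$max_elongation - rows$max_elongation_mean[r]) /
                rows$max_elongation_mean[r], 0.05)
    expect_lt(abs(q$asymmetry - rows$asymmetry_mean[r]), 0.03)
  }
})

test_that("refining the frame rate barely moves frequency and asymmetry", {
  q10 <- quantify_trace(sim_scrunch(f = 0.72, A = 0.52, a = 0.59,
                                    duration = 30, fps = 10)$trace)
  q20 <- quantify_trace(sim_scrunch(f = 0.72, A = 0.52, a = 0.59,
                                    duration = 30, fps = 20)$trace)
  expect_lt(abs(q10$frequency - q20$frequency) / q10$frequency, 0.01)
  expect_lt(abs(q10$asymmetry - q20$asymmetry) / q10$asymmetry, 0.01)
})

test_that("prepending gliding does not change the summary", {
  base <- quantify_trace(sim_scrunch(duration = 20)$trace)
  led <- quantify_trace(sim_scrunch(duration = 25, lead = 5)$trace)
  expect_lt(abs(base$frequency - led$frequency), 0.01)
  expect_lt(abs(base$max_elongation - led$max_elongation), 0.01)
  expect_lt(abs(base$asymmetry - led$asymmetry), 0.015)
  expect_identical(base$n_cycles, led$n_cycles)
})

test_that("scrunch counting skips the initial contraction", {
  expect_identical(count_scrunches(length_trace(rep(3, 100), 10)), 0L)

  # one long contraction only
  ramp <- length_trace(seq(120, 60, length.out = 60), 10)
  expect_identical(count_scrunches(ramp), 0L)

  # initial contraction, then seven clean cycles
  sim <- sim_scrunch(f = 0.5, duration = 14)
  osc <- sim$trace$lengths  # starts at the trough
  y <- c(seq(120, 60.5, length.out = 10), osc)
  tr <- length_trace(y, 10)
  expect_identical(count_scrunches(tr), 7L)
})

test_that("population summaries average per-worm speeds", {
  s1 <- summary_from_row(0.6, 0.5, 0.6)   # speed 0.30
  s2 <- summary_from_row(1.0, 0.5, 0.6)   # speed 0.50
  pop <- batch_summarize(list(s1, s2))
  expect_equal(pop$mean[pop$parameter == "speed"], 0.4)
  expect_true(all(pop$sd_defined))

  single <- batch_summarize(list(s1))
  expect_true(all(single$sd == 0))
  expect_false(any(single$sd_defined))
})

test_that("population means recover the generating distribution", {
  set.seed(21)
  sims <- lapply(1:9, function(i) {
    f <- max(0.2, stats::rnorm(1, 0.72, 0.08))
    A <- min(0.9, max(0.1, stats::rnorm(1, 0.52, 0.04)))
    a <- min(0.9, max(0.1, stats::rnorm(1, 0.59, 0.03)))
    list(truth = c(f = f, A = A),
         q = quantify_trace(sim_scrunch(f, A, a, duration = 30,
                                        noise = 0.01, seed = 300 + i)$trace))
  })
  pop <- batch_summarize(lapply(sims, `[[`, "q"))
  freq <- pop[pop$parameter == "frequency", ]
  expect_lt(abs(freq$mean - 0.72), 2 * 0.08 / sqrt(9) + 0.02)
})
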