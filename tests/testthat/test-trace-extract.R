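make_stack <- function(frames, fps = 10) image_stack(frames, fps)

test_that("auto background subtraction zeroes static scenes", {
  f <- matrix(100, 20, 30)
  st <- make_stack(list(f, f, f))
  out <- subtract_background(st, "auto")
  expect_true(all(unlist(out$frames) == 0))
})

test_that("explicit background equal to a frame zeroes that frame", {
  f1 <- matrix(runif(600, 0, 255), 20, 30)
  f2 <- matrix(runif(600, 0, 255), 20, 30)
  out <- subtract_background(make_stack(list(f1, f2)), f1)
  expect_true(all(out$frames[[1]] == 0))
  expect_error(subtract_background(make_stack(list(f1)), matrix(0, 5, 5)),
               "shape")
})

test_that("worm pixels dominate the difference image on a gradient scene", {
  # clip long enough that the drifting worm occupies each pixel for well
  # under half the frames, keeping the temporal-median background clean
  p <- gait_preset("scrunching_dj", duration_s = 12, fps = 4, noise_sd = 0)
  sim <- generate_length_trace(p)
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  gradient <- outer(seq_len(nrow(r$stack$frames[[1]])) * 0.2,
                    seq_len(ncol(r$stack$frames[[1]])) * 0.05, "+")
  st <- image_stack(lapply(r$stack$frames, function(f) f + gradient),
                    r$stack$fps)
  diffst <- subtract_background(st, "auto")
  for (i in c(1L, 25L, 49L)) {
    peak <- which(diffst$frames[[i]] == max(diffst$frames[[i]]),
                  arr.ind = TRUE)[1, ]
    expect_true(r$truth$masks[[i]][peak[1], peak[2]])
  }
})

test_that("segmentation recovers the rendered mask and flags blanks", {
  p <- gait_preset("scrunching_dj", duration_s = 2, fps = 5, noise_sd = 0)
  sim <- generate_length_trace(p)
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  diffst <- subtract_background(r$stack,
                                matrix(200, nrow(r$stack$frames[[1]]),
                                       ncol(r$stack$frames[[1]])))
  m <- segment_worm(diffst$frames[[3]])
  expect_true(m$valid)
  expect_identical(m$mask, r$truth$masks[[3]])

  blank <- segment_worm(matrix(0, 30, 30))
  expect_false(blank$valid)
})

test_that("the largest component wins and small ones are dropped", {
  frame <- matrix(0, 60, 60)
  frame[2:26, 2:21] <- 255     # 500-px blob
  frame[41:48, 41:45] <- 255   # 40-px blob
  m <- segment_worm(frame, method = "fixed", threshold = 128, min_area = 50)
  expect_true(m$valid)
  expect_identical(m$area, 500L)
  expect_false(any(m$mask[41:48, 41:45]))

  both_small <- matrix(0, 20, 20)
  both_small[2:5, 2:5] <- 255
  expect_false(segment_worm(both_small, method = "fixed", threshold = 128,
                            min_area = 50)$valid)
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(scrunchr:::label_components8(m)), 1L)
  m[5, 1] <- TRUE  # isolated pixel: its own component
  expect_identical(max(scrunchr:::label_components8(m)), 2L)
})

test_that("equivalent-ellipse length matches the closed form on an ellipse", {
  mask <- ellipse_mask(50, 10)
  fit <- fit_ellipse_major_axis(mask)
  expect_lt(abs(fit$length - 100) / 100, 0.02)  # discretization only
  expect_gt(fit$eccentricity, 0.97)
})

test_that("ellipse fit equals the brute-force pixel-covariance oracle", {
  masks <- list(rect_mask(90, 10), ellipse_mask(30, 7), ellipse_mask(12, 12))
  set.seed(11)
  for (k in 1:10) {
    m <- matrix(stats::runif(400) < 0.4, 20, 20)
    if (sum(m) >= 2) masks[[length(masks) + 1]] <- m
  }
  for (m in masks)
    expect_equal(fit_ellipse_major_axis(m)$length, brute_force_major_axis(m),
                 tolerance = 1e-12)
})

test_that("ellipse fit agrees with the moment features of EBImage", {
  mask <- ellipse_mask(40, 9)
  ours <- fit_ellipse_major_axis(mask)$length
  ebi <- EBImage::computeFeatures.moment(
    matrix(as.integer(mask), nrow(mask), ncol(mask)))[1, "m.majoraxis"]
  expect_equal(ours, unname(ebi), tolerance = 1e-8)
})

test_that("length is invariant to translation and 90-degree rotation", {
  base <- ellipse_mask(35, 8)
  shifted <- matrix(FALSE, nrow(base) + 10, ncol(base) + 14)
  shifted[7 + seq_len(nrow(base)), 11 + seq_len(ncol(base))] <- base
  rotated <- t(base)
  l0 <- fit_ellipse_major_axis(base)$length
  expect_equal(fit_ellipse_major_axis(shifted)$length, l0)
  expect_equal(fit_ellipse_major_axis(rotated)$length, l0)
})

test_that("degenerate masks are handled", {
  expect_error(fit_ellipse_major_axis(matrix(FALSE, 5, 5)), "empty")
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  fit <- fit_ellipse_major_axis(single)
  expect_true(fit$degenerate)
  expect_identical(fit$length, 0)
})

test_that("extracted lengths track the ground truth frame by frame", {
  p <- gait_params("scrunching", frequency_hz = 0.5, max_elongation = 0.5,
                   asymmetry = 0.6, gliding_length = 100, duration_s = 10,
                   fps = 5, noise_sd = 0)
  sim <- generate_length_trace(p)
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  tr <- extract_length_trace(subtract_background(r$stack, "auto"))
  expect_length(tr$lengths, length(sim$truth$true_length_px))
  rel <- abs(tr$lengths - sim$truth$true_length_px) /
    sim$truth$true_length_px
  expect_lt(max(rel), 0.02)
})

test_that("extraction scales linearly with worm length", {
  render_one <- function(gl) {
    sim <- generate_length_trace(gait_preset("gliding", gliding_length = gl,
                                             duration_s = 1, fps = 5))
    r <- render_worm_stack(sim$trace, sim$truth,
                           render_params(frame_width = 400,
                                         frame_height = 60))
    tr <- extract_length_trace(
      subtract_background(r$stack, matrix(200, 60, 400)))
    mean(tr$lengths)
  }
  ratio <- render_one(150) / render_one(100)
  expect_lt(abs(ratio - 1.5), 0.045)
})

test_that("a blank frame is interpolated and flagged", {
  p <- gait_preset("scrunching_dj", duration_s = 2, fps = 5, noise_sd = 0)
  sim <- generate_length_trace(p)
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  d <- dim(r$stack$frames[[1]])
  frames <- r$stack$frames
  frames[[5]] <- matrix(200, d[1], d[2])  # worm vanished
  tr <- extract_length_trace(
    subtract_background(image_stack(frames, 5), matrix(200, d[1], d[2])))
  expect_identical(sum(tr$interpolated), 1L)
  expect_true(tr$interpolated[5])
  expect_gt(tr$lengths[5], 0)
})

test_that("a two-frame stack yields a two-sample trace", {
  sim <- generate_length_trace(gait_preset("gliding", duration_s = 0.2,
                                           fps = 5))
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  bg <- matrix(200, nrow(r$stack$frames[[1]]), ncol(r$stack$frames[[1]]))
  tr <- extract_length_trace(subtract_background(r$stack, bg))
  expect_length(tr$lengths, 2L)
  expect_error(extract_length_trace(
    image_stack(r$stack$frames[1], 5)), "2 frames")
})

test_that("too many invalid frames abort extraction", {
  sim <- generate_length_trace(gait_preset("gliding", duration_s = 1,
                                           fps = 10))
  r <- render_worm_stack(sim$trace, sim$truth, render_params())
  d <- dim(r$stack$frames[[1]])
  frames <- r$stack$frames
  for (i in 3:7) frames[[i]] <- matrix(200, d[1], d[2])
  expect_error(extract_length_trace(
    subtract_background(image_stack(frames, 10), matrix(200, d[1], d[2])),
    max_invalid_fraction = 0.2), "segmented")
})

test_that("normalization arithmetic and window validation behave", {
  tr <- length_trace(rep(200, 50), fps = 10)
  nrm <- normalize_by_gliding(tr, c(0, 2))
  expect_true(all(nrm$lengths == 1))
  expect_identical(nrm$gliding_baseline, 200)

  tr2 <- length_trace(rep(c(180, 220), 10), fps = 2)
  nrm2 <- normalize_by_gliding(tr2, c(0, 9.5))
  expect_identical(nrm2$gliding_baseline, 200)

  expect_error(normalize_by_gliding(tr, c(0, 0.3)), "1 s")
  expect_error(normalize_by_gliding(tr, c(3, 20)), "span")
})

test_that("the auto gliding window lands in the gliding segment", {
  p <- gait_params("scrunching", frequency_hz = 0.72, max_elongation = 0.52,
                   asymmetry = 0.59, duration_s = 20, fps = 10,
                   noise_sd = 0.01, gliding_lead_s = 6, seed = 9L)
  sim <- generate_length_trace(p)
  nrm <- normalize_by_gliding(sim$trace, "auto")
  win <- attr(nrm, "gliding_window")
  expect_lte(win[2], 6)  # oscillation starts at 6 s
  expect_lt(abs(nrm$gliding_baseline - 100), 2)
})
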