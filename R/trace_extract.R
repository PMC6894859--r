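# 8-connected component labeling via vectorized frontier flood fill.
# EBImage::bwlabel is 4-connected, which splits diagonally touching pixels;
# worm silhouettes need the 8-connected rule.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  unvisited <- rep(FALSE, h * w)
  unvisited[fg] <- TRUE
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  lab <- 0L
  repeat {
    seed <- which.max(unvisited)
    if (!unvisited[seed]) break
    lab <- lab + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    labels[seed] <- lab
    while (length(frontier) > 0L) {
      rows <- ((frontier - 1L) %% h) + 1L
      nb <- rep(frontier, each = 8L) + offs
      nbr <- rep(rows, each = 8L) + drow
      ok <- nbr >= 1L & nbr <= h & nb >= 1L & nb <= h * w
      nb <- unique(nb[ok])
      nb <- nb[unvisited[nb]]
      unvisited[nb] <- FALSE
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

#' Subtract the background from an image stack
#'
#' @param stack an [image_stack()].
#' @param background either `"auto"` (per-pixel temporal median of the
#'   stack) or an explicit background raster of the same shape as the
#'   frames.
#' @return an [image_stack()] of absolute differences, clipped to the
#'   8-bit range.
#' @export
subtract_background <- function(stack, background = "auto") {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames[[1]])
  if (is.character(background) && identical(background, "auto")) {
    arr <- array(unlist(stack$frames), dim = c(d, length(stack$frames)))
    background <- apply(arr, c(1, 2), stats::median)
  } else {
    if (!is.matrix(background) || !all(dim(background) == d))
      stop("'background' must match the frame shape", call. = FALSE)
  }
  frames <- lapply(stack$frames, function(f)
    pmin(pmax(abs(f - background), 0), 255))
  image_stack(frames, stack$fps,
              source = paste0(stack$source, " [bg-subtracted]"))
}

#' Segment the worm in a background-subtracted frame
#'
#' Thresholds the frame (Otsu by default) and keeps the largest
#' 8-connected component; components smaller than `min_area` are rejected.
#' A frame with no component of at least `min_area` pixels is flagged
#' invalid (a trace gap) rather than raising an error.
#'
#' @param frame numeric matrix of 8-bit difference values.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold gray-level threshold for `method = "fixed"`.
#' @param min_area minimum component area in pixels.
#' @return object of class `worm_mask`: list with `mask` (logical matrix),
#'   `valid`, `area` and the `threshold` used.
#' @export
segment_worm <- function(frame, method = c("otsu", "fixed"),
                         threshold = NULL, min_area = 50) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame))
  if (method == "otsu") {
    rng <- range(frame)
    if (diff(rng) == 0)
      return(structure(list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
                            valid = FALSE, area = 0L,
                            threshold = NA_real_),
                       class = "worm_mask"))
    threshold <- EBImage::otsu(EBImage::Image(frame / 255),
                               range = c(0, 1), levels = 256) * 255
  } else if (is.null(threshold)) {
    stop("'threshold' is required for method = \"fixed\"", call. = FALSE)
  }
  bin <- frame > threshold
  labels <- label_components8(bin)
  nlab <- max(labels)
  if (nlab == 0L)
    return(structure(list(mask = bin & FALSE, valid = FALSE, area = 0L,
                          threshold = threshold), class = "worm_mask"))
  areas <- tabulate(labels[labels > 0L], nbins = nlab)
  best <- which.max(areas)
  if (areas[best] < min_area)
    return(structure(list(mask = bin & FALSE, valid = FALSE,
                          area = as.integer(areas[best]),
                          threshold = threshold), class = "worm_mask"))
  structure(list(mask = labels == best, valid = TRUE,
                 area = as.integer(areas[best]), threshold = threshold),
            class = "worm_mask")
}

#' Moment-based equivalent-ellipse major axis of a binary mask
#'
#' Fits the intensity-equivalent ellipse via image moments: the returned
#' length is `4 * sqrt(largest eigenvalue)` of the covariance matrix of
#' the foreground pixel coordinates (the ellipse with the same second
#' moments as the mask). This is the standard "fit ellipse" measurement of
#' common image-analysis software and has a closed-form oracle.
#'
#' @param mask logical matrix, or a `worm_mask` from [segment_worm()].
#' @return list with `length` (major axis, pixels), `minor` (minor axis),
#'   `axis_ratio` (minor/major), `eccentricity`, and `degenerate` (TRUE
#'   for a single-pixel mask, where the length is 0).
#' @export
fit_ellipse_major_axis <- function(mask) {
  if (inherits(mask, "worm_mask")) mask <- mask$mask
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  if (n == 1L)
    return(list(length = 0, minor = 0, axis_ratio = NA_real_,
                eccentricity = NA_real_, degenerate = TRUE))
  mu <- colMeans(idx)
  cc <- sweep(idx, 2, mu)
  cov2 <- crossprod(cc) / n           # population covariance of pixel coords
  ev <- eigen(cov2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  list(length = major, minor = minor,
       axis_ratio = if (major > 0) minor / major else NA_real_,
       eccentricity = if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else NA_real_,
       degenerate = FALSE)
}

#' Extract a body-length trace from an image stack
#'
#' Segments every frame and measures the worm length as the equivalent-
#' ellipse major axis. Frames where segmentation fails are filled by
#' linear interpolation between their valid neighbours (leading and
#' trailing invalid frames are dropped); the trace records which samples
#' were interpolated. Frames whose minor/major axis ratio exceeds
#' `bend_ratio_max` are flagged as bent, and the analysis-window selection
#' downstream avoids them.
#'
#' @param stack a background-subtracted [image_stack()] (see
#'   [subtract_background()]).
#' @param method,threshold,min_area segmentation options, see
#'   [segment_worm()].
#' @param bend_ratio_max minor/major ratio above which a frame is flagged
#'   as bent.
#' @param max_invalid_fraction maximum tolerated fraction of invalid
#'   frames before extraction errors out.
#' @param id trace identifier.
#' @return a [length_trace()] in pixels, with `interpolated` and
#'   `bend_flag` per sample.
#' @export
extract_length_trace <- function(stack, method = "otsu", threshold = NULL,
                                 min_area = 50, bend_ratio_max = 0.35,
                                 max_invalid_fraction = 0.2,
                                 id = "extracted") {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  lens <- rep(NA_real_, n)
  bend <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- segment_worm(stack$frames[[i]], method = method,
                      threshold = threshold, min_area = min_area)
    if (!m$valid) next
    fit <- fit_ellipse_major_axis(m)
    if (fit$degenerate || fit$length <= 0) next
    lens[i] <- fit$length
    bend[i] <- is.finite(fit$axis_ratio) && fit$axis_ratio > bend_ratio_max
  }
  valid <- which(!is.na(lens))
  if (length(valid) == 0L) stop("no frame could be segmented", call. = FALSE)
  first <- valid[1]; last <- valid[length(valid)]
  keep <- first:last
  lens <- lens[keep]; bend <- bend[keep]
  invalid <- is.na(lens)
  if (mean(invalid) > max_invalid_fraction)
    stop(sprintf("%.0f%% of frames could not be segmented (limit %.0f%%)",
                 100 * mean(invalid), 100 * max_invalid_fraction),
         call. = FALSE)
  if (any(invalid))
    lens[invalid] <- stats::approx(which(!invalid), lens[!invalid],
                                   xout = which(invalid))$y
  length_trace(lens, stack$fps, interpolated = invalid, bend_flag = bend,
               id = id)
}

#' Normalize a trace by its average gliding length
#'
#' Divides all lengths by the mean length over a gliding window. With
#' `window = "auto"` the baseline window is the lowest-variance sliding
#' window of width `window_width_s`, which on a gliding-then-oscillating
#' recording lands inside the gliding segment.
#'
#' @param trace a raw-pixel [length_trace()].
#' @param window `"auto"`, or a numeric `c(t0, t1)` interval in seconds.
#' @param window_width_s width of the auto-selected window, seconds.
#' @return the normalized [length_trace()] (lengths in body-length units,
#'   `gliding_baseline` set, and the selected window attached as attribute
#'   `"gliding_window"`).
#' @export
normalize_by_gliding <- function(trace, window = "auto",
                                 window_width_s = 3) {
  stopifnot(inherits(trace, "length_trace"))
  y <- trace$lengths
  n <- length(y)
  min_samples <- max(2L, ceiling(trace$fps))  # windows must span >= 1 s
  if (is.character(window) && identical(window, "auto")) {
    k <- min(n, max(min_samples, round(window_width_s * trace$fps) + 1L))
    cs <- cumsum(c(0, y)); cs2 <- cumsum(c(0, y^2))
    starts <- seq_len(n - k + 1L)
    sums <- cs[starts + k] - cs[starts]
    sums2 <- cs2[starts + k] - cs2[starts]
    vars <- (sums2 - sums^2 / k) / k
    s <- which.min(vars)
    sel <- s:(s + k - 1L)
  } else {
    if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2])
      stop("'window' must be \"auto\" or an increasing c(t0, t1)",
           call. = FALSE)
    if (window[1] < trace$times[1] - 1e-9 ||
        window[2] > trace$times[n] + 1e-9)
      stop("gliding window lies outside the trace span", call. = FALSE)
    sel <- which(trace$times >= window[1] - 1e-9 &
                 trace$times <= window[2] + 1e-9)
    if (length(sel) < min_samples)
      stop("gliding window must contain at least 1 s of samples",
           call. = FALSE)
  }
  baseline <- mean(y[sel])
  out <- trace
  out$lengths <- y / baseline
  out$normalized <- TRUE
  out$gliding_baseline <- baseline
  attr(out, "gliding_window") <- c(trace$times[sel[1]],
                                   trace$times[sel[length(sel)]])
  out
}
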