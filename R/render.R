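#' Image stack container
#'
#' @param frames list of equal-sized numeric matrices, 8-bit gray values
#'   in `[0, 255]`, rows = image height.
#' @param fps frame rate in frames per second.
#' @param source origin of the stack (file path or "synthetic").
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, fps, source = "synthetic") {
  stop_if_not_scalar_num(fps, "fps", positive = TRUE)
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == d),
               logical(1))
  if (!all(ok))
    stop("all frames must be matrices of identical dimensions", call. = FALSE)
  structure(list(frames = frames, fps = fps, source = source),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d @ %g fps (%s)\n",
              length(x$frames), d[1], d[2], x$fps, x$source))
  invisible(x)
}

#' Rendering parameters for synthetic worm frames
#'
#' Describes how a simulated worm is drawn: an elliptically tapered body
#' (an exact ellipse silhouette when straight) along an optionally
#' sinusoidally bent spine, dark on a light background, drifting across
#' the frame so that a temporal-median background estimate stays clean.
#' The elliptical taper is chosen so that the moment-based equivalent
#' ellipse of the silhouette has major axis equal to the true body length.
#'
#' @param frame_height,frame_width frame size in pixels; `NULL` auto-sizes
#'   from the trace (peak length, drift distance and a margin).
#' @param worm_width full body width in pixels at mid-body.
#' @param bend_amplitude peak lateral deflection of the spine as a fraction
#'   of the current body length (0 = straight).
#' @param worm_intensity,background_intensity 8-bit gray levels; the worm
#'   must be darker than the background.
#' @param background_noise_sd Gaussian noise SD in gray levels.
#' @param drift_bl_s drift speed of the worm across the frame, in body
#'   (gliding) lengths per second.
#' @param margin clearance in pixels kept between the worm and the frame
#'   border when auto-sizing.
#' @return object of class `render_params`.
#' @export
render_params <- function(frame_height = NULL, frame_width = NULL,
                          worm_width = 12, bend_amplitude = 0,
                          worm_intensity = 60, background_intensity = 200,
                          background_noise_sd = 0, drift_bl_s = 0.3,
                          margin = 20) {
  stop_if_not_scalar_num(worm_width, "worm_width", positive = TRUE)
  stop_if_not_scalar_num(bend_amplitude, "bend_amplitude", nonneg = TRUE)
  stop_if_not_scalar_num(background_noise_sd, "background_noise_sd",
                         nonneg = TRUE)
  stop_if_not_scalar_num(drift_bl_s, "drift_bl_s", nonneg = TRUE)
  if (worm_intensity >= background_intensity)
    stop("the worm must be darker than the background", call. = FALSE)
  structure(list(frame_height = frame_height, frame_width = frame_width,
                 worm_width = worm_width, bend_amplitude = bend_amplitude,
                 worm_intensity = worm_intensity,
                 background_intensity = background_intensity,
                 background_noise_sd = background_noise_sd,
                 drift_bl_s = drift_bl_s, margin = margin),
            class = "render_params")
}

#' Render a simulated worm into an 8-bit image stack
#'
#' Draws one connected worm silhouette per frame whose straight-line
#' end-to-end spine length equals that frame's true length (within the
#' pixel grid). The worm drifts along the frame's long axis at
#' `drift_bl_s` body lengths per second. Deterministic given `seed`.
#'
#' @param trace a [length_trace()] from [generate_length_trace()].
#' @param truth the matching `ground_truth` object.
#' @param render a [render_params()] object.
#' @param seed RNG seed for the background noise; defaults to the
#'   simulation seed + 1.
#' @return list with `stack` (an [image_stack()]) and `truth` (the input
#'   ground truth with per-frame logical masks attached as `masks`).
#' @export
render_worm_stack <- function(trace, truth, render = render_params(),
                              seed = NULL) {
  stopifnot(inherits(trace, "length_trace"), inherits(truth, "ground_truth"),
            inherits(render, "render_params"))
  if (is.null(seed)) seed <- truth$params$seed + 1L
  lens <- if (trace$normalized) trace$lengths * trace$gliding_baseline
          else trace$lengths
  n <- length(lens)
  l_max <- max(lens)
  gl <- truth$params$gliding_length
  drift_px_s <- render$drift_bl_s * gl
  travel <- drift_px_s * max(trace$times)
  w <- render$frame_width
  h <- render$frame_height
  if (is.null(w))
    w <- ceiling(l_max + travel + 2 * render$margin)
  if (is.null(h))
    h <- ceiling(max(render$worm_width + 2 * render$bend_amplitude * l_max +
                       2 * render$margin, 40))
  # worm must fit at peak length (plus bend) in every frame
  if (l_max + travel > w - 2 || render$worm_width +
        2 * render$bend_amplitude * l_max > h - 2)
    stop("worm does not fit inside the frame at peak length", call. = FALSE)
  cy <- (h + 1) / 2
  x0 <- 1 + (w - travel - l_max) / 2  # left end of worm at t = 0
  xs <- seq_len(w)
  ys <- seq_len(h)
  frames <- vector("list", n)
  masks <- vector("list", n)
  noise <- if (render$background_noise_sd > 0)
    with_seed(seed, stats::rnorm(n * h * w, 0, render$background_noise_sd))
  else NULL
  for (i in seq_len(n)) {
    len <- lens[i]
    cx <- x0 + drift_px_s * trace$times[i] + l_max / 2
    u <- (xs - cx) / (len / 2)                    # [-1, 1] along the spine
    inside_x <- abs(u) <= 1
    half_w <- numeric(w)
    half_w[inside_x] <- (render$worm_width / 2) *
      sqrt(pmax(0, 1 - u[inside_x]^2))
    dy <- numeric(w)
    if (render$bend_amplitude > 0)
      dy[inside_x] <- render$bend_amplitude * len *
        sin(pi * (u[inside_x] + 1) / 2)
    # mask[r, c]: |y_r - cy - dy_c| <= half_w_c
    mask <- abs(outer(ys - cy, dy, "-")) <=
      rep(half_w, each = h) & rep(inside_x, each = h)
    fr <- matrix(render$background_intensity, h, w)
    if (!is.null(noise))
      fr <- fr + matrix(noise[((i - 1) * h * w + 1):(i * h * w)], h, w)
    fr[mask] <- render$worm_intensity
    frames[[i]] <- pmin(pmax(round(fr), 0), 255)
    masks[[i]] <- mask
  }
  truth$masks <- masks
  list(stack = image_stack(frames, trace$fps, source = "synthetic"),
       truth = truth)
}

#' Read an image stack from disk
#'
#' Accepts a multi-page TIFF path, or a character vector / glob of numbered
#' TIFF or PNG frame files (sorted numerically, not lexically).
#'
#' @param path file path, glob pattern, or vector of frame paths.
#' @param fps frame rate of the recording (required; not stored in the
#'   image files).
#' @return an [image_stack()] with 8-bit gray values in `[0, 255]`.
#' @export
read_image_stack <- function(path, fps) {
  stop_if_not_scalar_num(fps, "fps", positive = TRUE)
  paths <- path
  if (length(path) == 1L && !file.exists(path)) {
    paths <- Sys.glob(path)
    if (length(paths) == 0L)
      stop(sprintf("no files match '%s'", path), call. = FALSE)
  }
  if (length(paths) > 1L) {
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(paths))))
    if (!any(is.na(num))) paths <- paths[order(num)]
  }
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a * 255
  }
  ext <- tolower(tools::file_ext(paths[1]))
  frames <- if (length(paths) == 1L && ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, to_gray)
  } else {
    lapply(paths, function(p) {
      e <- tolower(tools::file_ext(p))
      img <- switch(e,
        png = png::readPNG(p),
        tif = , tiff = tiff::readTIFF(p),
        stop(sprintf("unsupported frame format '%s'", e), call. = FALSE))
      to_gray(img)
    })
  }
  image_stack(frames, fps, source = paste(paths[1],
    if (length(paths) > 1L) sprintf("(+%d frames)", length(paths) - 1L)
    else ""))
}

#' Write an image stack as a multi-page 8-bit TIFF
#'
#' @param stack an [image_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 255), path,
                  bits.per.sample = 8)
  invisible(path)
}
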