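#' Construct a body-length trace
#'
#' The central signal of the pipeline: worm body length sampled on a uniform
#' time grid with the first sample at t = 0.
#'
#' @param lengths numeric vector of strictly positive lengths (pixels, or
#'   body-length units once normalized).
#' @param fps sampling rate in frames per second.
#' @param normalized logical; `TRUE` once lengths have been divided by the
#'   gliding baseline.
#' @param gliding_baseline baseline length in pixels (set by
#'   [normalize_by_gliding()]).
#' @param interpolated logical vector flagging samples filled in by
#'   interpolation across segmentation failures.
#' @param bend_flag logical vector flagging frames where the worm silhouette
#'   was too bent for a straight-line length readout.
#' @param id trace identifier used in summaries and reports.
#'
#' @return an object of class `length_trace`: a list with elements `times`,
#'   `lengths`, `fps`, `normalized`, `gliding_baseline`, `interpolated`,
#'   `bend_flag` and `id`.
#' @export
length_trace <- function(lengths, fps, normalized = FALSE,
                         gliding_baseline = NA_real_,
                         interpolated = NULL, bend_flag = NULL,
                         id = "trace") {
  stop_if_not_scalar_num(fps, "fps", positive = TRUE)
  if (!is.numeric(lengths) || length(lengths) < 1L)
    stop("'lengths' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("trace lengths must be finite and strictly positive", call. = FALSE)
  n <- length(lengths)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  if (is.null(bend_flag)) bend_flag <- rep(FALSE, n)
  stopifnot(length(interpolated) == n, length(bend_flag) == n)
  structure(
    list(times = (seq_len(n) - 1) / fps,
         lengths = as.numeric(lengths),
         fps = fps,
         normalized = isTRUE(normalized),
         gliding_baseline = gliding_baseline,
         interpolated = as.logical(interpolated),
         bend_flag = as.logical(bend_flag),
         id = id),
    class = "length_trace")
}

#' @export
print.length_trace <- function(x, ...) {
  cat(sprintf(
    "<length_trace '%s'> %d samples @ %g fps (%.1f s), %s%s\n",
    x$id, length(x$lengths), x$fps, max(x$times),
    if (x$normalized) sprintf("normalized (baseline %.1f px)",
                              x$gliding_baseline)
    else "raw pixels",
    if (any(x$interpolated)) sprintf(", %d interpolated",
                                     sum(x$interpolated)) else ""))
  invisible(x)
}

#' Convert a length trace to a data frame
#'
#' @param x a [length_trace()].
#' @param ... unused.
#' @return data frame with columns `frame`, `time_s`, `length_px`,
#'   `length_norm`, `interpolated`, `bend_flag`.
#' @export
as.data.frame.length_trace <- function(x, ...) {
  raw <- if (x$normalized) x$lengths * x$gliding_baseline else x$lengths
  nrm <- if (x$normalized) x$lengths else rep(NA_real_, length(x$lengths))
  data.frame(frame = seq_along(x$lengths) - 1L,
             time_s = x$times,
             length_px = raw,
             length_norm = nrm,
             interpolated = x$interpolated,
             bend_flag = x$bend_flag)
}
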