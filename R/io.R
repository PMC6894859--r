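check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and write length-trace CSV files
#'
#' The trace CSV schema is `frame`, `time_s`, `length_px`, `length_norm`,
#' `interpolated`, `bend_flag`. Writing then reading preserves values to
#' full double precision.
#'
#' @param path CSV path.
#' @param fps frame rate override; by default inferred from the `time_s`
#'   column.
#' @return [read_trace_csv()]: a [length_trace()]; [write_trace_csv()]:
#'   the path, invisibly.
#' @export
read_trace_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("frame", "time_s", "length_px"), "trace CSV")
  if (is.null(fps)) {
    dt <- diff(df$time_s)
    if (length(dt) == 0L || any(dt <= 0))
      stop("cannot infer fps from 'time_s'; pass 'fps'", call. = FALSE)
    fps <- 1 / stats::median(dt)
  }
  normalized <- "length_norm" %in% names(df) && !all(is.na(df$length_norm))
  lengths <- if (normalized) df$length_norm else df$length_px
  baseline <- if (normalized) stats::median(df$length_px / df$length_norm)
              else NA_real_
  length_trace(
    lengths, fps, normalized = normalized, gliding_baseline = baseline,
    interpolated = if ("interpolated" %in% names(df))
      as.logical(df$interpolated) else NULL,
    bend_flag = if ("bend_flag" %in% names(df))
      as.logical(df$bend_flag) else NULL,
    id = tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_trace_csv
#' @param trace a [length_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "length_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a behavior score CSV
#'
#' Expects columns `condition`, `replicate`, `reviewer`, `worm`,
#' `interval`, `label` and validates them via [score_table()].
#'
#' @param path CSV path.
#' @return a [score_table()].
#' @export
read_score_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_table(df)
}

#' @rdname read_score_csv
#' @param table a [score_table()].
#' @export
write_score_csv <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct CSV
#'
#' Expects columns `sample`, `gene`, `bio_rep`, `tech_rep`, `ct`.
#'
#' @param path CSV path.
#' @return data frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample", "gene", "bio_rep", "tech_rep", "ct"),
                "Ct CSV")
  if (any(df$ct <= 0)) stop("all Cts must be > 0", call. = FALSE)
  df
}

#' Read a gait reference CSV
#'
#' Same schema as the packaged table, see [reference_gaits()].
#'
#' @param path CSV path.
#' @return a `reference_table` data frame.
#' @export
read_refs_csv <- function(path) reference_gaits(path)

#' Write a machine-readable provenance file
#'
#' Every pipeline run writes its resolved configuration (plus package
#' version and timestamp) next to its outputs so the run can be repeated.
#'
#' @param config named list of resolved parameters.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_provenance <- function(config, path) {
  payload <- list(
    package = "scrunchr",
    version = as.character(utils::packageVersion("scrunchr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

pipeline_defaults <- function() list(
  out_dir = ".",
  gait = "scrunching_dj",
  frequency_hz = NULL, max_elongation = NULL, asymmetry = NULL,
  gliding_length = 100, peak_factor = 1.2, noise_sd = 0,
  duration_s = 30, fps = 10, gliding_lead_s = 5,
  render = FALSE, worm_width = 12, bend_amplitude = 0,
  background_noise_sd = 0, drift_bl_s = 0.3,
  smooth_window_s = 0.3, prominence_frac = 0.10, min_period_s = 0.5,
  min_cycles = 4,
  species = "D_japonica", refs_path = NULL,
  seed = 1L)

#' Run the simulate-extract-quantify-classify pipeline
#'
#' Executes the full synthetic pipeline from one flat configuration:
#' simulate a recording (optionally rendering and re-extracting the trace
#' from images), normalize, quantify the gait parameters and classify the
#' gait. All intermediate artifacts (trace CSV, summary JSON,
#' classification CSV and a provenance file) are written to
#' `config$out_dir`. Unknown configuration keys are rejected before any
#' computation. All randomness flows from `config$seed`.
#'
#' @param config named list overriding the defaults (see
#'   `scrunchr:::pipeline_defaults()` for the full key set).
#' @return invisibly, a list with `trace`, `summary`, `classification`
#'   and the artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  preset_args <- list(name = cfg$gait, gliding_length = cfg$gliding_length,
                      peak_factor = cfg$peak_factor, noise_sd = cfg$noise_sd,
                      duration_s = cfg$duration_s, fps = cfg$fps,
                      gliding_lead_s = cfg$gliding_lead_s, seed = cfg$seed)
  for (key in c("frequency_hz", "max_elongation", "asymmetry"))
    if (!is.null(cfg[[key]])) preset_args[[key]] <- cfg[[key]]
  sim <- generate_length_trace(do.call(gait_preset, preset_args))
  trace <- sim$trace

  if (isTRUE(cfg$render)) {
    rp <- render_params(worm_width = cfg$worm_width,
                        bend_amplitude = cfg$bend_amplitude,
                        background_noise_sd = cfg$background_noise_sd,
                        drift_bl_s = cfg$drift_bl_s)
    rendered <- render_worm_stack(trace, sim$truth, rp)
    stack_path <- file.path(cfg$out_dir, "stack.tif")
    write_image_stack(rendered$stack, stack_path)
    diff_stack <- subtract_background(rendered$stack, "auto")
    trace <- extract_length_trace(diff_stack, id = trace$id)
  }

  norm <- normalize_by_gliding(trace, "auto")
  trace_path <- file.path(cfg$out_dir, "trace.csv")
  write_trace_csv(norm, trace_path)

  summary <- quantify_trace(norm, smooth_window_s = cfg$smooth_window_s,
                            prominence_frac = cfg$prominence_frac,
                            min_period_s = cfg$min_period_s,
                            min_cycles = cfg$min_cycles)
  summary_path <- file.path(cfg$out_dir, "summary.json")
  summary_payload <- if (inherits(summary, "insufficient_oscillation"))
    list(insufficient_oscillation = TRUE, n_cycles = summary$n_cycles)
  else summary[c("frequency", "max_elongation", "speed", "asymmetry",
                 "n_cycles", "window", "id")]
  jsonlite::write_json(summary_payload, summary_path, auto_unbox = TRUE,
                       digits = NA)

  refs <- if (is.null(cfg$refs_path)) reference_gaits()
          else reference_gaits(cfg$refs_path)
  cl <- classify_gait(summary, refs, cfg$species)
  cl_path <- file.path(cfg$out_dir, "classification.csv")
  utils::write.csv(
    data.frame(id = trace$id, species = cfg$species, label = cl$label,
               d_scrunching = unname(cl$z_distances["scrunching"]),
               d_peristalsis = unname(cl$z_distances["peristalsis"]),
               flags = paste(cl$flags, collapse = ";")),
    cl_path, row.names = FALSE)
  prov_path <- file.path(cfg$out_dir, "provenance.json")
  write_provenance(cfg[order(names(cfg))], prov_path)

  invisible(list(trace = norm, summary = summary, classification = cl,
                 paths = list(trace = trace_path, summary = summary_path,
                              classification = cl_path,
                              provenance = prov_path)))
}
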