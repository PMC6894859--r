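#' Load a gait reference table
#'
#' Per-species, per-gait parameter means, SDs and sample sizes used as
#' classification centroids and t-test references. The packaged default
#' contains the published scrunching references for both species (from
#' amputation experiments) and the S. mediterranea peristalsis reference.
#'
#' @param path CSV path with columns `species`, `gait`, `parameter`,
#'   `mean`, `sd`, `n`; `NULL` loads the packaged table.
#' @return data frame of class `reference_table`.
#' @export
reference_gaits <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_gaits.csv",
                        package = "scrunchr", mustWork = TRUE)
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "gait", "parameter", "mean", "sd", "n")
  missing <- setdiff(required, names(refs))
  if (length(missing) > 0)
    stop(sprintf("reference table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(refs$sd <= 0)) stop("reference SDs must be > 0", call. = FALSE)
  if (any(refs$n < 2)) stop("reference n must be >= 2", call. = FALSE)
  class(refs) <- c("reference_table", "data.frame")
  refs
}

ref_entry <- function(refs, species, gait) {
  sub <- refs[refs$species == species & refs$gait == gait, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  pars <- c("frequency", "max_elongation", "speed", "asymmetry")
  if (!all(pars %in% sub$parameter)) return(NULL)
  sub <- sub[match(pars, sub$parameter), ]
  list(mean = stats::setNames(sub$mean, pars),
       sd = stats::setNames(sub$sd, pars),
       n = sub$n[1])
}

#' Two-sample t-test from summary statistics
#'
#' Compares a sample (mean, SD, N) against a reference entry without raw
#' data, as used when testing gait parameters against published values.
#' The Welch variant (default) uses the Welch-Satterthwaite degrees of
#' freedom; `"pooled"` is the classical equal-variance student's t-test.
#'
#' @param mean,sd,n sample summary statistics (`n >= 2`, `sd > 0`).
#' @param ref_mean,ref_sd,ref_n reference summary statistics.
#' @param variant `"welch"` or `"pooled"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_vs_reference <- function(mean, sd, n, ref_mean, ref_sd, ref_n,
                                variant = c("welch", "pooled"),
                                alternative = c("two.sided", "less",
                                                "greater")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (n < 2 || ref_n < 2) stop("both sample sizes must be >= 2",
                               call. = FALSE)
  if (sd <= 0 || ref_sd <= 0) stop("SDs must be > 0", call. = FALSE)
  if (variant == "welch") {
    v1 <- sd^2 / n; v2 <- ref_sd^2 / ref_n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n - 1) + v2^2 / (ref_n - 1))
  } else {
    sp2 <- ((n - 1) * sd^2 + (ref_n - 1) * ref_sd^2) / (n + ref_n - 2)
    se <- sqrt(sp2 * (1 / n + 1 / ref_n))
    df <- n + ref_n - 2
  }
  t <- (mean - ref_mean) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

#' Classify a gait summary as gliding, peristalsis or scrunching
#'
#' Deterministic nearest-centroid rule over the four gait parameters:
#' (1) gliding when the trace showed insufficient oscillation or its
#' maximum elongation is below `amplitude_floor`; (2) otherwise the label
#' of the reference gait minimizing the standardized Euclidean distance
#' `sqrt(sum_k ((x_k - mu_k)/sigma_k)^2)`; (3) a species lacking a
#' peristalsis reference borrows the other species' peristalsis entry;
#' (4) near-ties (distance difference below `tie_margin`) are broken by
#' the scrunching hallmark: asymmetry above `asym_threshold` means
#' scrunching. When the summary carries population statistics
#' (`sd`/`n` per parameter via `sample_sd`/`sample_n`), per-parameter
#' t-tests against the species' scrunching reference are attached as a
#' report (they do not drive the decision).
#'
#' @param summary a [summarize_gait()] result, or an
#'   `insufficient_oscillation` object from [select_window()].
#' @param refs a [reference_gaits()] table.
#' @param species `"D_japonica"` or `"S_mediterranea"` (any species
#'   present in `refs`).
#' @param amplitude_floor max-elongation below which the trace is called
#'   gliding.
#' @param asym_threshold asymmetry separating scrunching from peristalsis
#'   in near-ties.
#' @param tie_margin distance difference treated as a tie.
#' @param sample_sd,sample_n optional named per-parameter SDs and N for
#'   the t-test report (population summaries only).
#' @param t_variant t-test variant, see [t_test_vs_reference()].
#' @return object of class `gait_classification`: list with `label`,
#'   `z_distances`, `flags`, and optionally `t_tests`.
#' @export
classify_gait <- function(summary, refs, species,
                          amplitude_floor = 0.10, asym_threshold = 0.55,
                          tie_margin = 0.05, sample_sd = NULL,
                          sample_n = NULL, t_variant = "welch") {
  stopifnot(inherits(refs, "reference_table"))
  scrunch_ref <- ref_entry(refs, species, "scrunching")
  if (is.null(scrunch_ref))
    stop(sprintf("no scrunching reference for species '%s'", species),
         call. = FALSE)
  flags <- character(0)
  result <- function(label, d = c(scrunching = NA_real_,
                                  peristalsis = NA_real_)) {
    out <- list(label = label, z_distances = d, species = species,
                flags = flags)
    if (!is.null(sample_sd) && !is.null(sample_n) &&
        !inherits(summary, "insufficient_oscillation")) {
      pars <- c("frequency", "max_elongation", "speed", "asymmetry")
      out$t_tests <- lapply(stats::setNames(pars, pars), function(p)
        t_test_vs_reference(summary[[p]], sample_sd[[p]], sample_n,
                            scrunch_ref$mean[[p]], scrunch_ref$sd[[p]],
                            scrunch_ref$n, variant = t_variant))
    }
    class(out) <- "gait_classification"
    out
  }
  if (inherits(summary, "insufficient_oscillation")) {
    flags <- "insufficient_oscillation"
    return(result("gliding"))
  }
  if (summary$max_elongation < amplitude_floor) {
    flags <- "amplitude_floor"
    return(result("gliding"))
  }
  peri_ref <- ref_entry(refs, species, "peristalsis")
  if (is.null(peri_ref)) {
    other <- setdiff(unique(refs$species), species)
    for (sp in other) {
      peri_ref <- ref_entry(refs, sp, "peristalsis")
      if (!is.null(peri_ref)) { flags <- c(flags,
        sprintf("peristalsis_reference_from_%s", sp)); break }
    }
  }
  x <- c(frequency = summary$frequency,
         max_elongation = summary$max_elongation,
         speed = summary$speed, asymmetry = summary$asymmetry)
  zdist <- function(ref) sqrt(sum(((x - ref$mean) / ref$sd)^2))
  d <- c(scrunching = zdist(scrunch_ref),
         peristalsis = if (is.null(peri_ref)) NA_real_ else zdist(peri_ref))
  if (is.na(d["peristalsis"])) return(result("scrunching", d))
  label <- if (abs(d["scrunching"] - d["peristalsis"]) < tie_margin) {
    flags <- c(flags, "distance_tie")
    if (summary$asymmetry > asym_threshold) "scrunching" else "peristalsis"
  } else {
    names(d)[which.min(d)]
  }
  result(label, d)
}

#' @export
print.gait_classification <- function(x, ...) {
  cat(sprintf("<gait_classification> %s (%s)\n", x$label, x$species))
  if (!all(is.na(x$z_distances)))
    cat(sprintf("  distances: scrunching %.2f, peristalsis %.2f\n",
                x$z_distances["scrunching"], x$z_distances["peristalsis"]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a batch of summaries
#'
#' Applies [classify_gait()] to each summary and reports label counts per
#' condition.
#'
#' @param summaries list of [summarize_gait()] results (or
#'   `insufficient_oscillation` objects).
#' @param refs a [reference_gaits()] table.
#' @param species character vector (recycled) of species per summary.
#' @param condition optional character vector (recycled) of condition
#'   labels.
#' @param ... passed on to [classify_gait()].
#' @return data frame with one row per summary (`condition`, `species`,
#'   `label`, distances and flags); label counts per condition are
#'   attached as attribute `"label_counts"`.
#' @export
classify_batch <- function(summaries, refs, species,
                           condition = "all", ...) {
  n <- length(summaries)
  species <- rep_len(species, n)
  condition <- rep_len(condition, n)
  rows <- lapply(seq_len(n), function(i) {
    cl <- classify_gait(summaries[[i]], refs, species[i], ...)
    data.frame(condition = condition[i], species = species[i],
               label = cl$label,
               d_scrunching = unname(cl$z_distances["scrunching"]),
               d_peristalsis = unname(cl$z_distances["peristalsis"]),
               flags = paste(cl$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  attr(out, "label_counts") <- table(out$condition, out$label)
  out
}
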