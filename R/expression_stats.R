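#' Primer efficiency from a standard curve
#'
#' Ordinary least-squares fit of Ct against log10(dilution) over a serial
#' dilution of pooled cDNA; the amplification efficiency follows from the
#' slope as `(10^(-1/slope) - 1) * 100` (a perfect doubling per cycle
#' gives slope -1/log10(2) = -3.3219 and 100% efficiency).
#'
#' @param points data frame with columns `log10_dilution` and `ct`
#'   (mean Ct per dilution point).
#' @return list with `slope`, `intercept`, `efficiency_percent`,
#'   `r_squared`.
#' @export
primer_efficiency <- function(points) {
  required <- c("log10_dilution", "ct")
  missing <- setdiff(required, names(points))
  if (length(missing) > 0)
    stop(sprintf("'points' is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(points) < 3L)
    stop("need at least 3 dilution points", call. = FALSE)
  if (stats::var(points$log10_dilution) == 0)
    stop("dilution points must vary", call. = FALSE)
  fit <- stats::lm(ct ~ log10_dilution, data = points)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       efficiency_percent = (10^(-1 / slope) - 1) * 100,
       r_squared = r2)
}

#' Relative expression and knockdown by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale; per biological
#' replicate, `dCt = Ct(target) - Ct(housekeeping)` within each sample
#' and `ddCt = dCt(RNAi) - dCt(control)`. Relative expression is
#' `2^(-ddCt)` per biological replicate; the reported value is the mean
#' of the per-replicate relative expressions (`average = "ddct"` instead
#' averages ddCt before exponentiating). Knockdown is
#' `(1 - relative expression) * 100`.
#'
#' @param records data frame with columns `sample`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct` (all Cts > 0).
#' @param target_gene,housekeeping_gene gene names present in both
#'   samples.
#' @param control_sample,rnai_sample sample names.
#' @param average `"expression"` (default) or `"ddct"`.
#' @return object of class `knockdown_result`: list with `per_bio_rep`
#'   (data frame of dCt, ddCt and relative expression per biological
#'   replicate), `relative_expression`, `knockdown_percent`.
#' @export
ddct_knockdown <- function(records, target_gene, housekeeping_gene,
                           control_sample, rnai_sample,
                           average = c("expression", "ddct")) {
  average <- match.arg(average)
  required <- c("sample", "gene", "bio_rep", "tech_rep", "ct")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0)
    stop(sprintf("Ct table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(records$ct <= 0)) stop("all Cts must be > 0", call. = FALSE)
  mean_ct <- function(sample, gene) {
    sub <- records[records$sample == sample & records$gene == gene, ,
                   drop = FALSE]
    if (nrow(sub) == 0L)
      stop(sprintf("no Ct records for gene '%s' in sample '%s'",
                   gene, sample), call. = FALSE)
    tapply(sub$ct, sub$bio_rep, mean)
  }
  ct <- list(
    control_target = mean_ct(control_sample, target_gene),
    control_hk = mean_ct(control_sample, housekeeping_gene),
    rnai_target = mean_ct(rnai_sample, target_gene),
    rnai_hk = mean_ct(rnai_sample, housekeeping_gene))
  reps <- names(ct$control_target)
  same <- vapply(ct, function(x) identical(sort(names(x)), sort(reps)),
                 logical(1))
  if (!all(same))
    stop("biological replicate structure differs across samples/genes",
         call. = FALSE)
  reps <- sort(reps)
  dct_control <- ct$control_target[reps] - ct$control_hk[reps]
  dct_rnai <- ct$rnai_target[reps] - ct$rnai_hk[reps]
  ddct <- dct_rnai - dct_control
  rel <- 2^(-ddct)
  rel_mean <- if (average == "expression") mean(rel) else 2^(-mean(ddct))
  structure(
    list(per_bio_rep = data.frame(bio_rep = reps,
                                  dct_control = unname(dct_control),
                                  dct_rnai = unname(dct_rnai),
                                  ddct = unname(ddct),
                                  relative_expression = unname(rel)),
         relative_expression = rel_mean,
         knockdown_percent = (1 - rel_mean) * 100),
    class = "knockdown_result")
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat(sprintf(
    "<knockdown_result> relative expression %.3f (knockdown %.1f%%) over %d bio replicate(s)\n",
    x$relative_expression, x$knockdown_percent, nrow(x$per_bio_rep)))
  invisible(x)
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' Generates control and RNAi Ct records for one target and one
#' housekeeping gene with a known true relative expression: the RNAi
#' target Ct is shifted by `-log2(true_rel_expr)` cycles. Each biological
#' replicate receives a shared random plate offset (which delta-delta-Ct
#' must cancel) and each well i.i.d. Gaussian Ct noise.
#'
#' @param true_rel_expr true relative expression in (0, 1].
#' @param n_bio,n_tech biological and technical replicates.
#' @param ct_noise_sd per-well Ct noise SD in cycles.
#' @param base_ct,hk_ct control-sample target and housekeeping Cts.
#' @param seed RNG seed.
#' @return data frame with columns `sample`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @export
simulate_ct_records <- function(true_rel_expr, n_bio = 2, n_tech = 3,
                                ct_noise_sd = 0.1, base_ct = 24,
                                hk_ct = 18, seed = 1L) {
  if (true_rel_expr <= 0 || true_rel_expr > 1)
    stop("'true_rel_expr' must lie in (0, 1]", call. = FALSE)
  shift <- -log2(true_rel_expr)
  grid <- expand.grid(sample = c("control", "rnai"),
                      gene = c("target", "housekeeping"),
                      bio_rep = seq_len(n_bio),
                      tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    plate_offset <- stats::rnorm(n_bio, 0, 0.5)
    true_ct <- ifelse(grid$gene == "housekeeping", hk_ct,
                      base_ct + ifelse(grid$sample == "rnai", shift, 0))
    grid$ct <- true_ct + plate_offset[grid$bio_rep] +
      stats::rnorm(nrow(grid), 0, ct_noise_sd)
  })
  grid
}
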