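check_plate <- function(plate) {
  need <- c("gene_id", "sample_id", "replicate", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss) > 0)
    stop2("qPCR plate is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(plate$ct))) stop2("non-finite Ct value in plate")
  invisible(plate)
}

# technical replicates averaged within each (gene, sample) well
well_means <- function(plate) {
  stats::aggregate(ct ~ gene_id + sample_id, data = plate, FUN = mean)
}

#' Relative quantification by the delta-delta Ct method
#'
#' Technical replicates are averaged within each well first; each biological
#' sample then contributes one `dCt = Ct_target - Ct_normalizer`. Group
#' `dCt`s are averaged per line at the chosen day, `ddCt` is their contrast
#' difference, and the fold change is `2^(-ddCt)` (or `(1+E)^(-ddCt)` with
#' an efficiency from a standard curve). Biological samples are the unit of
#' variance: the standard error combines the two group variances of per-
#' sample `dCt` (Welch), giving a t-based p-value.
#'
#' @param plate qPCR plate data.frame (gene_id, sample_id, replicate, ct).
#' @param meta sample sheet mapping sample_id to (line, day).
#' @param gene target gene_id.
#' @param day day label.
#' @param contrast two line labels, numerator group first; defaults to
#'   (Ross708, Illinois) order.
#' @param normalizer control gene_id; defaults to the plate's
#'   `"normalizer"` attribute.
#' @param efficiency optional amplification efficiency E; fold base becomes
#'   `1 + E` instead of 2.
#' @return list of class `fold_change`: `gene_id`, `day`, `contrast`,
#'   `ddct`, `fold`, `se`, `df`, `p_value`, `n` (per-group biological n).
#'   `se`/`p_value` are `NA` when a group has a single biological replicate.
#' @export
delta_delta <- function(plate, meta, gene, day, contrast = NULL,
                        normalizer = attr(plate, "normalizer"),
                        efficiency = NULL) {
  check_plate(plate)
  check_meta(meta)
  if (is.null(normalizer)) stop2("no normalizer given and none on the plate")
  if (is.null(contrast)) contrast <- meta_lines(meta)
  if (length(contrast) != 2) stop2("contrast must name two lines")
  wm <- well_means(plate)
  group_dct <- function(line) {
    ids <- intersect(meta_samples(meta, day, line), unique(wm$sample_id))
    if (length(ids) == 0)
      stop2("no plated samples for line '", line, "' at ", day)
    tgt <- wm$ct[wm$gene_id == gene & wm$sample_id %in% ids]
    nrm <- wm$ct[wm$gene_id == normalizer & wm$sample_id %in% ids]
    tgt_ids <- wm$sample_id[wm$gene_id == gene & wm$sample_id %in% ids]
    nrm_ids <- wm$sample_id[wm$gene_id == normalizer & wm$sample_id %in% ids]
    common <- intersect(tgt_ids, nrm_ids)
    if (length(common) < length(tgt_ids) || length(common) == 0)
      stop2("normalizer '", normalizer, "' well missing for sample(s): ",
            paste(setdiff(tgt_ids, nrm_ids), collapse = ", "))
    tgt[match(common, tgt_ids)] - nrm[match(common, nrm_ids)]
  }
  d1 <- group_dct(contrast[1])
  d2 <- group_dct(contrast[2])
  ddct <- mean(d1) - mean(d2)
  base <- if (is.null(efficiency)) 2 else 1 + efficiency
  fold <- base^(-ddct)
  n <- c(length(d1), length(d2)); names(n) <- contrast
  if (any(n < 2)) {
    se <- df <- p <- NA_real_
  } else {
    v1 <- stats::var(d1); v2 <- stats::var(d2)
    se2 <- v1 / n[1] + v2 / n[2]
    se <- sqrt(se2)
    if (se2 == 0) {
      df <- NA_real_
      p <- if (ddct == 0) 1 else 0
    } else {
      df <- se2^2 / ((v1 / n[1])^2 / (n[1] - 1) + (v2 / n[2])^2 / (n[2] - 1))
      p <- 2 * stats::pt(-abs(ddct) / se, df)
    }
  }
  structure(list(gene_id = gene, day = day, contrast = contrast,
                 ddct = ddct, fold = unname(fold), se = se, df = df,
                 p_value = p, n = n),
            class = "fold_change")
}

#' Fold changes for every target gene on a plate
#'
#' Applies [delta_delta()] to each non-normalizer gene at each requested
#' day and stacks the results.
#'
#' @inheritParams delta_delta
#' @param days day labels (default: all days of the plated samples).
#' @return data.frame: gene_id, day, ddct, fold, se, p_value.
#' @export
qpcr_fold_changes <- function(plate, meta, contrast = NULL,
                              normalizer = attr(plate, "normalizer"),
                              days = NULL, efficiency = NULL) {
  check_plate(plate)
  days <- days %||% unique(meta$day[meta$sample_id %in% plate$sample_id])
  targets <- setdiff(unique(plate$gene_id), normalizer)
  rows <- list()
  for (day in days) {
    for (g in targets) {
      fc <- delta_delta(plate, meta, g, day, contrast = contrast,
                        normalizer = normalizer, efficiency = efficiency)
      rows[[paste(g, day)]] <- data.frame(
        gene_id = g, day = day, ddct = fc$ddct, fold = fc$fold,
        se = fc$se, p_value = fc$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(quantity); the amplification efficiency
#' is `E = 10^(-1/slope) - 1` (E = 1 means perfect doubling each cycle).
#' Curves with non-negative slope, or with E outside (0, 1.1], are flagged
#' invalid/implausible rather than rejected.
#'
#' @param quantities template quantities (e.g. copy numbers), all > 0,
#'   with >= 3 distinct values spanning >= 2 log10 units.
#' @param cts observed Ct values, same length.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `valid`.
#' @export
fit_standard_curve <- function(quantities, cts) {
  if (length(quantities) != length(cts))
    stop2("quantities and cts differ in length")
  if (any(quantities <= 0)) stop2("quantities must be positive")
  lq <- log10(quantities)
  if (length(unique(lq)) < 3 || diff(range(lq)) < 2)
    stop2("need >= 3 distinct quantities spanning >= 2 log10 units")
  fit <- stats::lm(cts ~ lq)
  slope <- unname(stats::coef(fit)[2])
  eff <- 10^(-1 / slope) - 1
  valid <- slope < 0 && eff > 0 && eff <= 1.1
  if (slope >= 0)
    warning("standard curve has non-negative slope; assay invalid")
  else if (!valid)
    warning(sprintf("implausible efficiency %.2f from slope %.3f", eff, slope))
  tss <- sum((cts - mean(cts))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = eff,
                 r_squared = if (tss == 0) 1
                             else 1 - sum(stats::residuals(fit)^2) / tss,
                 valid = valid),
            class = "standard_curve")
}

#' RNA-seq vs qPCR concordance of fold changes
#'
#' Pairs per-gene, per-day RNA-seq log2 ratios with qPCR `-ddCt` (both are
#' log2 fold-change estimates of the same contrast) and reports their
#' Pearson and Spearman correlations.
#'
#' @param de_records data.frame with gene_id, day, log2_ratio (e.g. the
#'   `all` table of a [call_de()] day), or a `de_result`.
#' @param fold_changes data.frame from [qpcr_fold_changes()].
#' @return list: `pearson`, `spearman`, `n`, and the paired `table`.
#' @export
rnaseq_qpcr_concordance <- function(de_records, fold_changes) {
  if (inherits(de_records, "de_result"))
    de_records <- do.call(rbind, lapply(de_records, `[[`, "all"))
  need <- c("gene_id", "day", "log2_ratio")
  if (!all(need %in% names(de_records)))
    stop2("de_records must have columns ", paste(need, collapse = ", "))
  tab <- merge(de_records[, need],
               fold_changes[, c("gene_id", "day", "ddct")],
               by = c("gene_id", "day"))
  if (nrow(tab) == 0) stop2("no genes measured by both platforms")
  if (nrow(tab) < 3) stop2("need >= 3 genes measured by both platforms")
  tab$qpcr_log2_fold <- -tab$ddct
  list(pearson = stats::cor(tab$log2_ratio, tab$qpcr_log2_fold),
       spearman = stats::cor(tab$log2_ratio, tab$qpcr_log2_fold,
                             method = "spearman"),
       n = nrow(tab), table = tab)
}
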