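#' Simulation-based power estimate for the full DE pipeline
#'
#' Repeatedly simulates a dataset under a design, runs the complete
#' pipeline (RPKM, expression filter, differential-enrichment call) and
#' scores the calls against the planted truth. Sensitivity is the fraction
#' of planted DE genes flagged (pooled over days); the false-positive rate
#' is the fraction of non-planted analysis-set genes flagged. The FPR of
#' the p-value criterion alone (`fpr_p`) and of the |z| > k criterion alone
#' (`fpr_z`) are also recorded, since the conjunction necessarily flags
#' fewer genes than either. Per-simulation seeds are `seed + i` for
#' simulation i, so any cell is independently reproducible.
#'
#' @param config a [sim_config()] describing the design (its `seed` field
#'   is overridden per simulation).
#' @param params a [de_params()].
#' @param n_sim number of simulations (>= 10).
#' @param seed master seed.
#' @param threshold expression filter threshold in RPKM.
#' @param days days to score (default: both).
#' @return list of class `power_result`: per-simulation table `sims`,
#'   `sensitivity`/`fpr`/`fpr_p`/`fpr_z` means, matching `se_*` Monte-Carlo
#'   standard errors, and the design.
#' @export
estimate_power <- function(config, params = de_params(), n_sim = 50,
                           seed = 42, threshold = 0.1, days = NULL) {
  if (!inherits(config, "sim_config")) stop2("config must be a sim_config")
  if (n_sim < 10) stop2("need n_sim >= 10")
  if (config$n_reps_per_cell < 2)
    stop2("design with a single replicate per cell: the per-gene test is undefined")
  sims <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    ds <- simulate_dataset(cfg)
    rpkm <- compute_rpkm(ds$counts, ds$genes, ds$samples,
                         allow_depth_below_colsum = TRUE)
    filt <- filter_expressed(rpkm, ds$samples, threshold)
    use_days <- days %||% unique(ds$samples$day)
    de <- call_de(rpkm, ds$samples, filt$genes, params, days = use_days)
    tp <- fp <- n_pos <- n_null <- 0
    fp_p <- fp_z <- 0
    for (day in use_days) {
      planted <- ds$truth$gene_id[ds$truth[[paste0("de_", day)]]]
      flagged <- de[[day]]$records$gene_id
      tab <- de[[day]]$all
      nulls <- setdiff(tab$gene_id, planted)
      tp <- tp + length(intersect(flagged, planted))
      n_pos <- n_pos + length(planted)
      fp <- fp + length(intersect(flagged, nulls))
      n_null <- n_null + length(nulls)
      null_rows <- tab$gene_id %in% nulls
      fp_p <- fp_p + sum(tab$p_value[null_rows] < params$alpha)
      fp_z <- fp_z + sum(abs(tab$z[null_rows]) > params$k)
    }
    sims[[i]] <- data.frame(
      sim = i,
      sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
      fpr = fp / n_null, fpr_p = fp_p / n_null, fpr_z = fp_z / n_null)
  }
  sims <- do.call(rbind, sims)
  mc <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(mean = NA_real_, se = NA_real_)
    else c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  s <- mc(sims$sensitivity); f <- mc(sims$fpr)
  fp_ <- mc(sims$fpr_p); fz <- mc(sims$fpr_z)
  structure(list(sims = sims,
                 sensitivity = s[["mean"]], se_sensitivity = s[["se"]],
                 fpr = f[["mean"]], se_fpr = f[["se"]],
                 fpr_p = fp_[["mean"]], se_fpr_p = fp_[["se"]],
                 fpr_z = fz[["mean"]], se_fpr_z = fz[["se"]],
                 n_sim = n_sim, config = config, params = params,
                 seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("Power over %d simulations (n=%d/line, depth %s, ",
                     "phi=%.3g, effect %.3g log2):\n"),
              x$n_sim, x$config$n_reps_per_cell,
              paste(format(x$config$depths, big.mark = ","), collapse = "/"),
              x$config$dispersion, x$config$effect_log2))
  cat(sprintf("  sensitivity %.3f (SE %.3g), FPR %.4f (SE %.2g)\n",
              x$sensitivity, x$se_sensitivity, x$fpr, x$se_fpr))
  invisible(x)
}

#' Power over a grid of designs
#'
#' Runs [estimate_power()] for each row of a design table. Cell j uses the
#' base seed `seed + 10000 * j`, so each cell reproduces independently.
#'
#' @param designs data.frame whose columns override [sim_config()] fields;
#'   recognized: `n_reps_per_cell`, `depth` (single uniform library depth),
#'   `effect_log2`, `dispersion`, `frac_de`.
#' @param config base [sim_config()].
#' @inheritParams estimate_power
#' @return long-format data.frame: the design columns plus
#'   `sensitivity`, `se_sensitivity`, `fpr`, `se_fpr`, `cell_seed`.
#' @export
power_grid <- function(designs, config = sim_config(), params = de_params(),
                       n_sim = 20, seed = 42, threshold = 0.1) {
  if (!is.data.frame(designs) || nrow(designs) == 0)
    stop2("designs must be a non-empty data.frame")
  rows <- vector("list", nrow(designs))
  for (j in seq_len(nrow(designs))) {
    cfg <- config
    for (f in intersect(c("n_reps_per_cell", "effect_log2", "dispersion",
                          "frac_de"), names(designs)))
      cfg[[f]] <- designs[[f]][j]
    if ("depth" %in% names(designs)) cfg$depths <- designs$depth[j]
    cfg$n_reps_per_cell <- as.integer(cfg$n_reps_per_cell)
    cell_seed <- seed + 10000 * j
    pr <- estimate_power(cfg, params, n_sim = n_sim, seed = cell_seed,
                         threshold = threshold)
    rows[[j]] <- cbind(designs[j, , drop = FALSE],
                       data.frame(sensitivity = pr$sensitivity,
                                  se_sensitivity = pr$se_sensitivity,
                                  fpr = pr$fpr, se_fpr = pr$se_fpr,
                                  cell_seed = cell_seed))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
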