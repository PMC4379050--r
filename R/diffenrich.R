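#' Parameters of the differential-enrichment rule
#'
#' The rule flags a gene as differentially enriched at a day when its log2
#' between-line RPKM ratio lies more than `k` standard deviations from the
#' mean ratio across expressed genes AND its per-gene p-value is below
#' `alpha` (a conjunction; the defaults k = 2, alpha = 0.05 are the study's
#' published rule).
#'
#' @param k SD multiplier (> 0).
#' @param alpha p-value threshold in (0, 1).
#' @param epsilon pseudocount in RPKM added to both group means before the
#'   ratio (guards zero denominators).
#' @param test per-gene test: `"welch"` (Welch two-sample t on
#'   log2(RPKM + epsilon)) or a function `(x, y) -> p`.
#' @param mtc multiple-testing mode, `"none"` (raw p, the study's choice) or
#'   `"BH"` (Benjamini-Hochberg adjusted p compared to alpha).
#' @param sd_scope genes over which the ratio mean/SD are computed:
#'   `"expressed"` (post-filter, default) or `"all"`.
#' @return list of class `de_params`.
#' @export
de_params <- function(k = 2, alpha = 0.05, epsilon = 0.01,
                      test = "welch", mtc = c("none", "BH"),
                      sd_scope = c("expressed", "all")) {
  mtc <- match.arg(mtc)
  sd_scope <- match.arg(sd_scope)
  if (!is.finite(k) || k <= 0) stop2("de_params: k must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop2("de_params: alpha must be in (0, 1)")
  if (!is.finite(epsilon) || epsilon <= 0)
    stop2("de_params: epsilon must be > 0")
  if (!is.function(test) && !identical(test, "welch"))
    stop2("de_params: test must be \"welch\" or a function(x, y) -> p")
  structure(list(k = k, alpha = alpha, epsilon = epsilon, test = test,
                 mtc = mtc, sd_scope = sd_scope), class = "de_params")
}

#' Per-gene log2 between-line RPKM ratios at one day
#'
#' `r_i = log2((mean RPKM line1 + epsilon) / (mean RPKM line2 + epsilon))`
#' over that day's samples, with line1 = Ross708 (or the alphabetically
#' first line for other vocabularies).
#'
#' @param rpkm RPKM matrix.
#' @param meta sample sheet.
#' @param day day label to compare within.
#' @param epsilon pseudocount in RPKM.
#' @param genes optional gene subset (defaults to all rows).
#' @return named numeric vector of finite log2 ratios.
#' @export
log2_ratios <- function(rpkm, meta, day, epsilon = 0.01, genes = NULL) {
  check_meta(meta)
  lines <- meta_lines(meta)
  if (is.null(genes)) genes <- rownames(rpkm)
  m <- rpkm[genes, , drop = FALSE]
  m1 <- row_group_means(m, intersect(colnames(m), meta_samples(meta, day, lines[1])))
  m2 <- row_group_means(m, intersect(colnames(m), meta_samples(meta, day, lines[2])))
  r <- log2((m1 + epsilon) / (m2 + epsilon))
  names(r) <- genes
  r
}

# Row-wise Welch two-sample t-test. x, y: matrices with genes as rows.
# Returns data.frame(t, df, p). Degenerate rows (zero variance in both
# groups): p = 1 when the means are equal, p = 0 otherwise.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2 || ny < 2) stop2("Welch test needs >= 2 values per group")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {
    p[deg] <- ifelse(mx[deg] == my[deg], 1, 0)
    t[deg] <- ifelse(mx[deg] == my[deg], 0, Inf * sign(mx - my)[deg])
    df[deg] <- NA_real_
  }
  data.frame(t = t, df = df, p = p)
}

#' Per-gene two-group test on log-transformed expression
#'
#' Default is the Welch (unequal-variance) two-sample t-test on
#' log2(RPKM + epsilon), two-sided.
#'
#' @param x,y replicate RPKM values for the two groups (>= 2 each).
#' @param test `"welch"` or a function `(x, y) -> p` applied to the
#'   log-transformed values.
#' @param epsilon pseudocount in RPKM.
#' @return two-sided p-value in \[0, 1\].
#' @export
per_gene_test <- function(x, y, test = "welch", epsilon = 0.01) {
  lx <- log2(x + epsilon); ly <- log2(y + epsilon)
  if (is.function(test)) return(test(lx, ly))
  welch_rows(matrix(lx, 1), matrix(ly, 1))$p
}

#' Call differentially enriched genes per day
#'
#' For each day, computes per-gene log2 between-line ratios of mean RPKM
#' over the expressed gene set, standardizes them against the day's mean and
#' SD of ratios, tests each gene with the per-gene test, and flags genes
#' satisfying BOTH `|r_i - rbar| > k * s_r` and `p < alpha`. The enriched
#' line is the side of the mean the ratio falls on.
#'
#' @param rpkm RPKM matrix.
#' @param meta sample sheet (two lines; >= 2 replicates per line per day).
#' @param expressed character vector of expressed gene ids (from
#'   [filter_expressed()]); the analysis set.
#' @param params a [de_params()].
#' @param days days to analyze (default: all days in `meta`).
#' @return list of class `de_result`, one element per day, each holding
#'   \describe{
#'     \item{all}{data.frame over the analysis set: gene_id, day, group mean
#'       RPKMs, log2_ratio, z, p_value, enriched_line.}
#'     \item{records}{the flagged subset, sorted by |z| descending (ties by
#'       gene_id).}
#'     \item{r_mean, r_sd}{the day's ratio mean and SD.}
#'     \item{n_enriched}{named per-line flagged counts.}
#'   }
#'   The `de_params` used and the line labels are attached as attributes.
#' @export
call_de <- function(rpkm, meta, expressed, params = de_params(),
                    days = NULL) {
  check_meta(meta)
  if (!inherits(params, "de_params")) stop2("params must come from de_params()")
  lines <- meta_lines(meta)
  days <- days %||% unique(meta$day)
  miss <- setdiff(expressed, rownames(rpkm))
  if (length(miss) > 0)
    stop2("expressed genes absent from the RPKM matrix: ",
          paste(utils::head(miss, 5), collapse = ", "))
  eps <- params$epsilon
  out <- list()
  for (day in days) {
    ids1 <- meta_samples(meta, day, lines[1])
    ids2 <- meta_samples(meta, day, lines[2])
    if (length(ids1) < 2 || length(ids2) < 2)
      stop2("need >= 2 replicates per line at ", day)
    sub <- rpkm[expressed, , drop = FALSE]
    m1 <- row_group_means(sub, ids1)
    m2 <- row_group_means(sub, ids2)
    r <- log2((m1 + eps) / (m2 + eps))
    if (params$sd_scope == "all") {
      r_ref <- log2_ratios(rpkm, meta, day, eps)
      r_mean <- mean(r_ref); r_sd <- stats::sd(r_ref)
    } else {
      r_mean <- mean(r); r_sd <- stats::sd(r)
    }
    if (is.function(params$test)) {
      l1 <- log2(sub[, ids1, drop = FALSE] + eps)
      l2 <- log2(sub[, ids2, drop = FALSE] + eps)
      p <- vapply(seq_len(nrow(sub)),
                  function(i) params$test(l1[i, ], l2[i, ]), numeric(1))
    } else {
      p <- welch_rows(log2(sub[, ids1, drop = FALSE] + eps),
                      log2(sub[, ids2, drop = FALSE] + eps))$p
    }
    p_use <- if (params$mtc == "BH") stats::p.adjust(p, "BH") else p
    if (r_sd == 0) {
      warning("degenerate ratio SD of 0 at ", day, "; no genes flagged")
      z <- rep(0, length(r))
      flag <- rep(FALSE, length(r))
    } else {
      z <- (r - r_mean) / r_sd
      flag <- abs(r - r_mean) > params$k * r_sd & p_use < params$alpha
    }
    enriched <- ifelse(!flag, "none", ifelse(r > r_mean, lines[1], lines[2]))
    all_df <- data.frame(gene_id = expressed, day = day,
                         mean_rpkm_line1 = m1, mean_rpkm_line2 = m2,
                         log2_ratio = r, z = z, p_value = p,
                         enriched_line = enriched,
                         row.names = NULL, stringsAsFactors = FALSE)
    names(all_df)[names(all_df) == "mean_rpkm_line1"] <-
      paste0("mean_rpkm_", lines[1])
    names(all_df)[names(all_df) == "mean_rpkm_line2"] <-
      paste0("mean_rpkm_", lines[2])
    rec <- all_df[flag, , drop = FALSE]
    rec <- rec[order(-abs(rec$z), rec$gene_id), , drop = FALSE]
    rownames(rec) <- NULL
    n_enr <- c(sum(rec$enriched_line == lines[1]),
               sum(rec$enriched_line == lines[2]))
    names(n_enr) <- lines
    out[[day]] <- list(all = all_df, records = rec,
                       r_mean = r_mean, r_sd = r_sd, n_enriched = n_enr)
  }
  structure(out, class = "de_result", params = params, lines = lines)
}

#' Union of per-day enriched gene sets
#'
#' Genes differentially enriched in at least one condition; a gene flagged
#' on both days is counted once.
#'
#' @param de a `de_result` from [call_de()].
#' @return character vector of gene ids.
#' @export
de_union <- function(de) {
  stopifnot(inherits(de, "de_result"))
  sort(unique(unlist(lapply(de, function(d) d$records$gene_id),
                     use.names = FALSE)))
}

#' @export
print.de_result <- function(x, ...) {
  cat("Differential enrichment across", length(x), "day(s)\n")
  for (day in names(x)) {
    n <- x[[day]]$n_enriched
    cat(sprintf("  %s: %d enriched (%s), ratio mean %.4f, SD %.4f\n",
                day, sum(n), paste(names(n), n, sep = "=", collapse = ", "),
                x[[day]]$r_mean, x[[day]]$r_sd))
  }
  cat("Union:", length(de_union(x)), "genes\n")
  invisible(x)
}
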