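#' Cross-line expression concordance at one day
#'
#' Ordinary least-squares fit of one line's per-gene mean RPKM on the
#' other's (Illinois on Ross708 by default vocabulary), optionally on
#' log2(RPKM + epsilon). The untransformed fit mirrors an all-gene RPKM
#' scatter, where a handful of very highly expressed genes dominate the fit.
#'
#' @param rpkm RPKM matrix.
#' @param meta sample sheet.
#' @param day day label.
#' @param log_scale fit on log2(RPKM + epsilon) instead of raw RPKM.
#' @param epsilon pseudocount used when `log_scale = TRUE`.
#' @param genes optional gene subset (defaults to all rows).
#' @return list of class `concordance_fit`: `day`, `slope`, `intercept`,
#'   `r_squared`, `n_genes`, plus the per-gene means `x` (line 1) and `y`
#'   (line 2).
#' @export
line_concordance <- function(rpkm, meta, day, log_scale = FALSE,
                             epsilon = 0.01, genes = NULL) {
  check_meta(meta)
  lines <- meta_lines(meta)
  if (is.null(genes)) genes <- rownames(rpkm)
  if (length(genes) < 3) stop2("need >= 3 genes for a concordance fit")
  m <- rpkm[genes, , drop = FALSE]
  x <- row_group_means(m, meta_samples(meta, day, lines[1]))
  y <- row_group_means(m, meta_samples(meta, day, lines[2]))
  if (log_scale) {
    x <- log2(x + epsilon)
    y <- log2(y + epsilon)
  }
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(day = day,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_genes = length(genes), x = x, y = y,
                 lines = lines, log_scale = log_scale),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf("%s: %s ~ %s over %d genes%s\n", x$day, x$lines[2],
              x$lines[1], x$n_genes, if (x$log_scale) " (log2 scale)" else ""))
  cat(sprintf("  slope %.4f, intercept %.4f, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Hierarchical clustering of differentially enriched genes
#'
#' Agglomerative clustering of samples (columns) and of genes (rows) on
#' log2(RPKM + epsilon) restricted to the union of enriched genes, with
#' average linkage and Euclidean distance by default, heights on a distance
#' scale. Rows can be z-standardized for the gene dendrogram; constant rows
#' are dropped with a warning under standardization. Rows and columns are
#' sorted by label before clustering so the result is invariant to input
#' order.
#'
#' @param rpkm RPKM matrix.
#' @param meta sample sheet.
#' @param genes the gene subset to cluster (e.g. [de_union()] output).
#' @param method linkage passed to [stats::hclust()].
#' @param metric distance passed to [stats::dist()].
#' @param standardize z-standardize rows for the gene dendrogram.
#' @param epsilon pseudocount in RPKM.
#' @return list of class `cluster_result`: `sample_hclust`, `gene_hclust`
#'   (both `hclust` objects), and `genes` actually clustered.
#' @export
cluster_de_genes <- function(rpkm, meta, genes, method = "average",
                             metric = "euclidean", standardize = TRUE,
                             epsilon = 0.01) {
  check_meta(meta)
  if (length(genes) < 1) stop2("gene subset is empty")
  if (ncol(rpkm) < 2) stop2("need >= 2 samples to cluster")
  miss <- setdiff(genes, rownames(rpkm))
  if (length(miss) > 0)
    stop2("genes absent from the RPKM matrix: ",
          paste(utils::head(miss, 5), collapse = ", "))
  m <- log2(rpkm[sort(genes), sort(colnames(rpkm)), drop = FALSE] + epsilon)

  sample_hc <- stats::hclust(stats::dist(t(m), method = metric),
                             method = method)
  gm <- m
  if (standardize) {
    sds <- apply(gm, 1, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0),
              " constant row(s) before standardization")
      gm <- gm[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    gm <- (gm - rowMeans(gm)) / sds
  }
  gene_hc <- if (nrow(gm) >= 2)
    stats::hclust(stats::dist(gm, method = metric), method = method)
  else NULL
  structure(list(sample_hclust = sample_hc, gene_hclust = gene_hc,
                 genes = rownames(gm)),
            class = "cluster_result")
}

#' Membership of the top split of a dendrogram
#'
#' Cuts an `hclust` tree into its two outermost clusters, e.g. to check
#' whether the first split of the sample dendrogram separates lines or days.
#'
#' @param hc an `hclust` object.
#' @return integer vector of cluster labels (1/2) named by leaf.
#' @export
top_split <- function(hc) {
  stats::cutree(hc, k = 2)
}

#' Write a dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
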