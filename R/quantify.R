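#' Convert gene-level counts to RPKM
#'
#' RPKM (reads per kilobase of transcript per million mapped reads) for gene
#' i in sample j is `1e9 * C_ij / (N_j * L_i)`, with `C` the read count, `N_j`
#' the library's total mapped reads (from the sample sheet, not the column
#' sum: unassigned mapped reads still belong in the denominator) and `L_i`
#' the gene length in bp.
#'
#' @param counts non-negative integer matrix, genes x samples, with gene ids
#'   as rownames and sample ids as colnames.
#' @param genes gene annotation data.frame with `gene_id` and `length_bp`.
#' @param meta sample sheet with `sample_id` and `total_mapped_reads`.
#' @param depth_from_colsums use column sums of `counts` as `N_j` instead of
#'   the sample sheet.
#' @param allow_depth_below_colsum skip the sanity check that `N_j` is at
#'   least the column sum.
#' @return numeric matrix of RPKM values on the same gene x sample grid.
#' @export
compute_rpkm <- function(counts, genes, meta,
                         depth_from_colsums = FALSE,
                         allow_depth_below_colsum = FALSE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop2("counts must be finite and non-negative")
  miss <- setdiff(rownames(counts), genes$gene_id)
  if (length(miss) > 0)
    stop2("no length for gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
  len <- genes$length_bp[match(rownames(counts), genes$gene_id)]
  if (any(is.na(len) | len <= 0))
    stop2("gene lengths must be positive; offending gene(s): ",
          paste(utils::head(rownames(counts)[is.na(len) | len <= 0], 5),
                collapse = ", "))
  if (depth_from_colsums) {
    depth <- colSums(counts)
  } else {
    check_meta(meta)
    miss <- setdiff(colnames(counts), meta$sample_id)
    if (length(miss) > 0)
      stop2("no mapped-read total for sample(s): ",
            paste(miss, collapse = ", "))
    depth <- meta$total_mapped_reads[match(colnames(counts), meta$sample_id)]
    low <- depth < colSums(counts)
    if (any(low) && !allow_depth_below_colsum)
      stop2("total_mapped_reads below the count column sum for: ",
            paste(colnames(counts)[low], collapse = ", "),
            " (set allow_depth_below_colsum = TRUE to override)")
  }
  rpkm <- 1e9 * sweep(counts, 2, depth, "/") / len
  dimnames(rpkm) <- dimnames(counts)
  rpkm
}

#' Apply the study's expression filter
#'
#' A gene counts as expressed when its mean RPKM strictly exceeds the
#' threshold (default 0.1 RPKM) in at least one (line, day) group; with
#' `per_sample = TRUE`, when any single sample exceeds it.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param meta sample sheet with `sample_id`, `line`, `day`.
#' @param threshold RPKM cutoff (strict `>`).
#' @param per_sample use per-sample instead of per-group-mean semantics.
#' @return list with `genes` (character vector of expressed gene ids),
#'   `n_total`, `n_expressed`, and the `threshold` used.
#' @export
filter_expressed <- function(rpkm, meta, threshold = 0.1,
                             per_sample = FALSE) {
  check_meta(meta)
  if (threshold < 0) stop2("threshold must be >= 0")
  miss <- setdiff(colnames(rpkm), meta$sample_id)
  if (length(miss) > 0)
    stop2("samples missing from sample sheet: ", paste(miss, collapse = ", "))
  if (per_sample) {
    keep <- apply(rpkm, 1, max) > threshold
  } else {
    grp <- interaction(meta$line[match(colnames(rpkm), meta$sample_id)],
                       meta$day[match(colnames(rpkm), meta$sample_id)],
                       drop = TRUE)
    if (any(table(grp) == 0)) stop2("empty (line, day) group")
    gm <- sapply(levels(grp), function(g)
      row_group_means(rpkm, which(grp == g)))
    keep <- apply(gm, 1, max) > threshold
  }
  list(genes = rownames(rpkm)[keep],
       n_total = nrow(rpkm),
       n_expressed = sum(keep),
       threshold = threshold)
}
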