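#' Read a gene-by-sample count matrix
#'
#' Tab-delimited with a header row; first column `gene_id`, remaining
#' columns one per sample.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop2(path, ": first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stop2(path, ": duplicate gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stop2(path, ": counts must be complete and non-negative")
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `line`, `day`, `total_mapped_reads`.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_meta(df)
}

#' Read gene lengths from a two-column TSV or a GTF/GFF file
#'
#' TSV route: header columns `gene_id` and `length_bp` (extra annotation
#' columns `symbol`, `entrez_id` are kept if present). GTF/GFF route
#' (extensions .gtf/.gff/.gff3, requires the rtracklayer package): a gene's
#' length is the number of bases covered by the union of its exons
#' (overlapping exons are merged; coordinates are 1-based inclusive).
#'
#' @param path file path.
#' @return data.frame: gene_id, symbol, entrez_id, length_bp.
#' @export
read_lengths <- function(path) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop2("reading GTF/GFF gene lengths requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0) stop2(path, ": no exon features")
    if (is.null(ex$gene_id)) stop2(path, ": exons carry no gene_id")
    by_gene <- split(ex, ex$gene_id)
    len <- vapply(by_gene,
                  function(g) sum(BiocGenerics::width(GenomicRanges::reduce(g))),
                  numeric(1))
    out <- data.frame(gene_id = names(len), symbol = NA_character_,
                      entrez_id = NA_character_,
                      length_bp = as.integer(len), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "length_bp") %in% names(df)))
      stop2(path, ": need columns gene_id, length_bp")
    if (!"symbol" %in% names(df)) df$symbol <- NA_character_
    if (!"entrez_id" %in% names(df)) df$entrez_id <- NA_character_
    out <- df[, c("gene_id", "symbol", "entrez_id", "length_bp")]
  }
  if (anyDuplicated(out$gene_id)) stop2(path, ": duplicate gene_id")
  if (any(is.na(out$length_bp)) || any(out$length_bp <= 0))
    stop2(path, ": lengths must be positive for every gene")
  rownames(out) <- NULL
  out
}

#' Read a qPCR plate table
#'
#' Columns: `gene_id`, `sample_id`, `replicate`, `ct`.
#'
#' @param path TSV file.
#' @param normalizer optional control gene_id to attach to the plate.
#' @return data.frame of class `qpcr_plate`.
#' @export
read_plate <- function(path, normalizer = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_plate(df)
  if (!is.null(normalizer)) {
    if (!normalizer %in% df$gene_id)
      stop2(path, ": normalizer '", normalizer, "' not on the plate")
    attr(df, "normalizer") <- normalizer
  }
  class(df) <- c("qpcr_plate", "data.frame")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a count or expression matrix as TSV
#'
#' @param m matrix with gene rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a matrix written by [write_matrix()]
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Write one day's enriched-gene table
#'
#' Column order follows the published supplementary layout: Entrez id, gene
#' symbol, enriched line, log2 ratio, the two group mean RPKMs, then the
#' individual per-library RPKM values for that day's samples.
#'
#' @param de_day one day's element of a [call_de()] result.
#' @param rpkm RPKM matrix (for the per-sample columns).
#' @param meta sample sheet.
#' @param genes gene annotation (for symbol/entrez id).
#' @param path output TSV.
#' @return the written data.frame, invisibly.
#' @export
write_de_table <- function(de_day, rpkm, meta, genes, path) {
  rec <- de_day$records
  day <- if (nrow(rec) > 0) rec$day[1] else de_day$all$day[1]
  ids <- meta$sample_id[meta$day == day]
  ann <- genes[match(rec$gene_id, genes$gene_id), , drop = FALSE]
  mean_cols <- grep("^mean_rpkm_", names(rec), value = TRUE)
  out <- data.frame(entrez_id = ann$entrez_id, symbol = ann$symbol,
                    enriched_line = rec$enriched_line,
                    log2_ratio = rec$log2_ratio,
                    rec[, mean_cols, drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  persample <- rpkm[rec$gene_id, ids, drop = FALSE]
  colnames(persample) <- paste0("rpkm_", ids)
  out <- cbind(out, as.data.frame(persample, optional = TRUE))
  rownames(out) <- NULL
  write_tsv(out, path)
  invisible(out)
}
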