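#' Write a simulated dataset to a directory of TSVs
#'
#' Emits `counts.tsv`, `samples.tsv`, `gene_lengths.tsv`, `truth.tsv` and,
#' when a qPCR plate is supplied, `qpcr.tsv` — the on-disk entry points of
#' the pipeline.
#'
#' @param ds a [simulate_dataset()] result.
#' @param outdir output directory (created if missing).
#' @param plate optional [simulate_qpcr()] plate.
#' @return `outdir`, invisibly.
#' @export
write_sim_dataset <- function(ds, outdir, plate = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(ds$counts, file.path(outdir, "counts.tsv"))
  write_tsv(ds$samples, file.path(outdir, "samples.tsv"))
  write_tsv(ds$genes, file.path(outdir, "gene_lengths.tsv"))
  write_tsv(ds$truth, file.path(outdir, "truth.tsv"))
  if (!is.null(plate)) write_tsv(plate, file.path(outdir, "qpcr.tsv"))
  invisible(outdir)
}

default_pipeline_config <- function() {
  list(counts = NULL, samples = NULL, lengths = NULL,
       term_map = NULL, plate = NULL, normalizer = NULL,
       outdir = "pipeline_out", threshold = 0.1,
       k = 2, alpha = 0.05, epsilon = 0.01, mtc = "none",
       cluster_method = "average", cluster_metric = "euclidean",
       min_instances = 10, depth_from_colsums = FALSE,
       allow_depth_below_colsum = FALSE, seed = 1L)
}

#' Run the full two-line comparison pipeline
#'
#' Orchestrates quantification, the expression filter, the per-day
#' differential-enrichment call, cross-line concordance fits, hierarchical
#' clustering of the enriched-gene union, and (when inputs are provided)
#' GO-slim term tallies and qPCR fold changes. Every stage's output lands
#' in the configured directory, the configuration is echoed to
#' `config_echo.yaml` for provenance, and the headline counters (genes
#' analyzed, genes expressed above threshold, per-line enriched counts per
#' day, union size, per-day R-squared) go to `summary.json`.
#'
#' @param config named list (or path to a YAML file holding one) with
#'   entries: `counts`, `samples`, `lengths` (required input paths),
#'   optional `term_map`, `plate` + `normalizer`, and the knobs `outdir`,
#'   `threshold`, `k`, `alpha`, `epsilon`, `mtc`, `cluster_method`,
#'   `cluster_metric`, `min_instances`, `depth_from_colsums`,
#'   `allow_depth_below_colsum`, `seed`.
#' @return the summary list, invisibly; outputs are written to
#'   `config$outdir` (rpkm.tsv, de_<day>.tsv, cluster/, tally.tsv,
#'   folds.tsv, summary.json).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  for (f in c("counts", "samples", "lengths")) {
    if (is.null(cfg[[f]])) stop2("pipeline config is missing '", f, "'")
    if (!file.exists(cfg[[f]])) stop2(f, " file not found: ", cfg[[f]])
  }
  counts <- read_counts(cfg$counts)
  meta <- read_samples(cfg$samples)
  genes <- read_lengths(cfg$lengths)
  miss <- setdiff(colnames(counts), meta$sample_id)
  if (length(miss) > 0)
    stop2("count columns missing from the sample sheet: ",
          paste(miss, collapse = ", "))
  miss <- setdiff(meta$sample_id, colnames(counts))
  if (length(miss) > 0)
    stop2("sample sheet entries missing from the counts: ",
          paste(miss, collapse = ", "))

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config_echo.yaml"))
  set.seed(cfg$seed)

  rpkm <- compute_rpkm(counts, genes, meta,
                       depth_from_colsums = cfg$depth_from_colsums,
                       allow_depth_below_colsum = cfg$allow_depth_below_colsum)
  write_matrix(rpkm, file.path(cfg$outdir, "rpkm.tsv"))
  filt <- filter_expressed(rpkm, meta, cfg$threshold)
  params <- de_params(k = cfg$k, alpha = cfg$alpha, epsilon = cfg$epsilon,
                      mtc = cfg$mtc)
  de <- call_de(rpkm, meta, filt$genes, params)
  for (day in names(de))
    write_de_table(de[[day]], rpkm, meta, genes,
                   file.path(cfg$outdir, paste0("de_", day, ".tsv")))

  conc <- lapply(names(de), function(day)
    line_concordance(rpkm, meta, day, genes = filt$genes))
  names(conc) <- names(de)

  union_genes <- de_union(de)
  if (length(union_genes) >= 2) {
    cl_dir <- file.path(cfg$outdir, "cluster")
    dir.create(cl_dir, showWarnings = FALSE)
    cl <- cluster_de_genes(rpkm, meta, union_genes,
                           method = cfg$cluster_method,
                           metric = cfg$cluster_metric)
    write_newick(cl$sample_hclust, file.path(cl_dir, "samples.nwk"))
    if (!is.null(cl$gene_hclust))
      write_newick(cl$gene_hclust, file.path(cl_dir, "genes.nwk"))
    write_tsv(data.frame(merge = seq_along(cl$sample_hclust$height),
                         height = cl$sample_hclust$height),
              file.path(cl_dir, "sample_merge_heights.tsv"))
  }

  tally <- NULL
  if (!is.null(cfg$term_map)) {
    map <- read_term_map(cfg$term_map)
    by_day <- lapply(de, function(d) d$records$gene_id)
    tally <- tally_terms(by_day, map, min_instances = cfg$min_instances)
    write_tsv(as.data.frame(tally), file.path(cfg$outdir, "tally.tsv"))
  }

  folds <- NULL
  if (!is.null(cfg$plate)) {
    plate <- read_plate(cfg$plate, normalizer = cfg$normalizer)
    folds <- qpcr_fold_changes(plate, meta)
    write_tsv(folds, file.path(cfg$outdir, "folds.tsv"))
  }

  summary <- list(
    n_genes = filt$n_total,
    n_expressed = filt$n_expressed,
    threshold_rpkm = cfg$threshold,
    de = lapply(de, function(d) list(
      n_enriched = sum(d$n_enriched),
      by_line = as.list(d$n_enriched),
      ratio_mean = d$r_mean, ratio_sd = d$r_sd)),
    union_de = length(union_genes),
    r_squared = lapply(conc, function(cc) cc$r_squared))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
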