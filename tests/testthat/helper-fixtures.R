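# Small in-code fixtures shared across test files.

# balanced two-line two-day sample sheet
tiny_meta <- function(nrep = 3, depth = 1e6) {
  grid <- expand.grid(rep = seq_len(nrep), line = c("Ross708", "Illinois"),
                      day = c("D6", "D21"), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_R%d", grid$day, grid$line, grid$rep),
             line = grid$line, day = grid$day,
             total_mapped_reads = depth, stringsAsFactors = FALSE)
}

# random RPKM-like matrix on a tiny_meta design
tiny_rpkm <- function(n_genes = 20, nrep = 3, seed = 1, meanlog = 2,
                      sdlog = 1) {
  meta <- tiny_meta(nrep)
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * nrow(meta), meanlog, sdlog), n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              meta$sample_id))
  list(rpkm = m, meta = meta)
}

# annotation table for a count/RPKM matrix
tiny_genes <- function(counts, lengths = NULL) {
  data.frame(gene_id = rownames(counts), symbol = rownames(counts),
             entrez_id = NA_character_,
             length_bp = lengths %||% rep(1000L, nrow(counts)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small low-noise simulated dataset for closed-loop tests
quick_sim <- function(n_genes = 200, frac_de = 0.05, effect_log2 = 3,
                      dispersion = 0.02, seed = 7, nrep = 6, depths = 1e6,
                      ...) {
  simulate_dataset(sim_config(n_genes = n_genes, n_reps_per_cell = nrep,
                              depths = depths, dispersion = dispersion,
                              frac_de = frac_de, effect_log2 = effect_log2,
                              seed = seed, ...))
}

sim_pipeline <- function(ds, threshold = 0.1, params = de_params()) {
  rpkm <- compute_rpkm(ds$counts, ds$genes, ds$samples,
                       allow_depth_below_colsum = TRUE)
  filt <- filter_expressed(rpkm, ds$samples, threshold)
  de <- call_de(rpkm, ds$samples, filt$genes, params)
  list(rpkm = rpkm, filt = filt, de = de)
}
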