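#' Configuration for the two-line, two-day RNA-seq simulator
#'
#' Bundles and validates every knob of [simulate_dataset()]. Defaults emulate
#' the study design the package targets: two broiler lines (Ross708 vs
#' Illinois) sampled at post-hatch days 6 and 21, six biological replicates
#' per cell, libraries sequenced to roughly 10 or 30 million mapped reads,
#' 15,945 annotated genes of which about 68\% are expressed.
#'
#' @param n_genes number of annotated genes (>= 10).
#' @param n_reps_per_cell biological replicates per (line, day) cell.
#' @param depths mapped-read totals per library; one value (uniform depth) or
#'   two, in which case day-6 libraries get `depths[1]` and day-21 libraries
#'   follow the study's mixed pattern: the first 4 Ross708 and first 2
#'   Illinois replicates at `depths[1]`, the remainder at `depths[2]`.
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param frac_de fraction of genes planted with a between-line effect,
#'   independently per day.
#' @param effect_log2 planted |log2 fold change| between lines.
#' @param frac_expressed fraction of genes with a nonzero baseline abundance.
#' @param abundance_sdlog log-normal sdlog of the baseline relative
#'   abundances of expressed genes; 0 makes all expressed genes equally
#'   abundant.
#' @param day_frac_de fraction of genes planted with a between-day effect on
#'   the baseline (shared by both lines).
#' @param day_effect_log2 planted |log2 fold change| between days.
#' @param shared_line_effects if `TRUE`, the same genes carry the same
#'   signed line effect on both days (persistent line differences); by
#'   default each day's affected subset is drawn independently, as the
#'   mostly-disjoint per-day enriched lists of a real two-age comparison
#'   suggest.
#' @param length_range gene length bounds in bp (lower bound >= 200); lengths
#'   are drawn log-uniformly over this range.
#' @param drop_one_d21_illinois drop the last day-21 Illinois replicate,
#'   mirroring the study's 11-library day-21 set (6 Ross708, 5 Illinois).
#' @param noise_free if `TRUE`, counts are the rounded expected counts
#'   (deterministic mode used by closed-loop tests).
#' @param seed integer RNG seed; the whole dataset is reproducible given it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 15945L,
                       n_reps_per_cell = 6L,
                       depths = c(1e7, 3e7),
                       dispersion = 0.05,
                       frac_de = 0.012,
                       effect_log2 = 2,
                       frac_expressed = 0.68,
                       abundance_sdlog = 1.5,
                       day_frac_de = 0.2,
                       day_effect_log2 = 1,
                       shared_line_effects = FALSE,
                       length_range = c(500L, 10000L),
                       drop_one_d21_illinois = FALSE,
                       noise_free = FALSE,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_reps_per_cell = as.integer(n_reps_per_cell),
              depths = as.numeric(depths),
              dispersion = as.numeric(dispersion),
              frac_de = as.numeric(frac_de),
              effect_log2 = as.numeric(effect_log2),
              frac_expressed = as.numeric(frac_expressed),
              abundance_sdlog = as.numeric(abundance_sdlog),
              day_frac_de = as.numeric(day_frac_de),
              day_effect_log2 = as.numeric(day_effect_log2),
              shared_line_effects = isTRUE(shared_line_effects),
              length_range = as.numeric(length_range),
              drop_one_d21_illinois = isTRUE(drop_one_d21_illinois),
              noise_free = isTRUE(noise_free),
              seed = as.integer(seed))
  num <- unlist(cfg[c("n_genes", "n_reps_per_cell", "depths", "dispersion",
                      "frac_de", "effect_log2", "frac_expressed",
                      "abundance_sdlog", "day_frac_de", "day_effect_log2",
                      "length_range", "seed")])
  if (any(!is.finite(num))) stop2("sim_config: non-finite value supplied")
  if (cfg$n_genes < 10) stop2("sim_config: n_genes must be >= 10")
  if (cfg$n_reps_per_cell < 1) stop2("sim_config: need >= 1 replicate")
  if (!length(cfg$depths) %in% c(1, 2) || any(cfg$depths <= 0))
    stop2("sim_config: depths must be 1 or 2 positive values")
  if (cfg$dispersion < 0) stop2("sim_config: dispersion must be >= 0")
  if (cfg$abundance_sdlog < 0) stop2("sim_config: abundance_sdlog must be >= 0")
  for (f in c("frac_de", "frac_expressed", "day_frac_de")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop2("sim_config: ", f, " must be in [0, 1]")
  }
  if (length(cfg$length_range) != 2 || cfg$length_range[1] < 200 ||
      diff(cfg$length_range) < 0)
    stop2("sim_config: length_range must be increasing with lower bound >= 200 bp")
  structure(cfg, class = "sim_config")
}

# sample sheet for the design encoded in a sim_config
sim_sample_sheet <- function(cfg) {
  rows <- list()
  for (day in DAYS) {
    for (line in LINES) {
      n <- cfg$n_reps_per_cell
      if (day == "D21" && line == "Illinois" && cfg$drop_one_d21_illinois)
        n <- n - 1L
      if (n < 1) next
      rep <- seq_len(n)
      depth1 <- cfg$depths[1]
      depth2 <- cfg$depths[length(cfg$depths)]
      # study pattern: all D6 shallow; at D21 the later-sequenced libraries
      # (Ross708 reps > 4, Illinois reps > 2) are deep
      depth <- if (day == "D6") rep(depth1, n)
               else ifelse(rep > (if (line == "Ross708") 4L else 2L),
                           depth2, depth1)
      rows[[paste(day, line)]] <- data.frame(
        sample_id = sprintf("%s_%s_R%d", day, line, rep),
        line = line, day = day, total_mapped_reads = depth,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a two-line, two-day RNA-seq count dataset with known truth
#'
#' Draws gene lengths log-uniformly, assigns a heavy-tailed (log-normal)
#' baseline relative abundance to the expressed fraction of genes, plants
#' signed between-line log2 effects on a per-day subset and between-day
#' effects on another subset, and samples negative-binomial counts whose
#' expected value for gene i in library j is `N_j * p_ij`, where `p_ij` is
#' gene i's share of the library's transcript pool:
#' `p_ij = lambda_i * 2^(s_j d_i / 2) * 2^(t_j b_i / 2) * L_i / sum_g(...)`,
#' with `s_j = +1` for Ross708 and `-1` for Illinois, `d_i` the planted
#' between-line log2 effect for sample j's day, `t_j = +1` at D21 and `-1`
#' at D6, and `b_i` the planted day effect. Splitting each effect
#' symmetrically (+/- half per group) keeps total library depth meaningful.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{counts}{integer gene x sample matrix.}
#'     \item{samples}{sample sheet (sample_id, line, day, total_mapped_reads).}
#'     \item{genes}{gene annotation (gene_id, symbol, entrez_id, length_bp).}
#'     \item{truth}{per-gene ground truth: baseline `lambda`, `expressed`
#'       flag, per-day DE flags `de_D6`/`de_D21`, signed planted log2
#'       effects `effect_D6`/`effect_D21` (positive = Ross708-enriched),
#'       and the signed day effect `day_effect` (positive = higher at D21).}
#'   }
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))

  len <- round(exp(stats::runif(n, log(cfg$length_range[1]),
                                log(cfg$length_range[2]))))
  n_expr <- round(cfg$frac_expressed * n)
  expressed <- rep(FALSE, n)
  expressed[sample.int(n, n_expr)] <- TRUE
  lambda <- numeric(n)
  lambda[expressed] <- stats::rlnorm(n_expr, meanlog = 1,
                                     sdlog = cfg$abundance_sdlog)

  n_de <- round(cfg$frac_de * n)
  if (n_de > n_expr)
    stop2("simulate_dataset: frac_de exceeds the expressed fraction")
  plant <- function(n_planted, magnitude) {
    eff <- numeric(n)
    if (n_planted > 0 && magnitude != 0) {
      idx <- sample(which(expressed), n_planted)
      eff[idx] <- sample(c(-1, 1), n_planted, replace = TRUE) * magnitude
    }
    eff
  }
  effect_d6 <- plant(n_de, cfg$effect_log2)
  effect_d21 <- if (cfg$shared_line_effects) effect_d6
                else plant(n_de, cfg$effect_log2)
  n_day <- round(cfg$day_frac_de * n)
  day_effect <- plant(n_day, cfg$day_effect_log2)

  meta <- sim_sample_sheet(cfg)
  s <- ifelse(meta$line == "Ross708", 1, -1)
  t <- ifelse(meta$day == "D21", 1, -1)
  counts <- matrix(0L, n, nrow(meta),
                   dimnames = list(gene_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    d <- if (meta$day[j] == "D6") effect_d6 else effect_d21
    x <- lambda * 2^(s[j] * d / 2) * 2^(t[j] * day_effect / 2) * len
    mu <- meta$total_mapped_reads[j] * x / sum(x)
    counts[, j] <- as.integer(
      if (cfg$noise_free) round(mu)
      else if (cfg$dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion))
  }

  genes <- data.frame(gene_id = gene_id, symbol = gene_id,
                      entrez_id = NA_character_, length_bp = as.integer(len),
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, length_bp = as.integer(len),
                      lambda = lambda, expressed = expressed,
                      de_D6 = effect_d6 != 0, effect_D6 = effect_d6,
                      de_D21 = effect_d21 != 0, effect_D21 = effect_d21,
                      day_effect = day_effect, stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = meta, genes = genes,
                 truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Simulate a qPCR plate from planted ground truth
#'
#' Generates Ct triplicates for a set of target genes plus a normalizer in
#' every sample of a design, from the same relative-expression model as
#' [simulate_dataset()] (without the length term: qPCR reads out transcript
#' concentration, not read share). The Ct of gene i in sample j is
#' `intercept - log2(x_ij) + N(0, ct_noise_sd)` per technical replicate.
#'
#' @param truth the `truth` data.frame of a [simulate_dataset()] result.
#' @param meta sample sheet covering the samples to plate.
#' @param genes gene_ids to assay (targets); the normalizer is added.
#' @param normalizer gene_id of the control gene; must be expressed and
#'   non-DE on both days (rejected otherwise).
#' @param intercept Ct of a gene with relative expression 1.
#' @param ct_noise_sd technical noise SD in cycles.
#' @param n_tech technical replicates per well.
#' @param seed RNG seed.
#' @return data.frame (gene_id, sample_id, replicate, ct) of class
#'   `qpcr_plate`, with the normalizer recorded in `attr(, "normalizer")`.
#' @export
simulate_qpcr <- function(truth, meta, genes, normalizer,
                          intercept = 30, ct_noise_sd = 0.25,
                          n_tech = 3L, seed = 1L) {
  check_meta(meta)
  idx <- match(normalizer, truth$gene_id)
  if (is.na(idx)) stop2("normalizer '", normalizer, "' not in truth")
  if (truth$de_D6[idx] || truth$de_D21[idx])
    stop2("normalizer '", normalizer, "' is flagged DE in truth; ",
          "pick a non-DE control gene")
  if (!truth$expressed[idx])
    stop2("normalizer '", normalizer, "' is not expressed")
  genes <- union(genes, normalizer)
  miss <- setdiff(genes, truth$gene_id)
  if (length(miss) > 0)
    stop2("genes not in truth: ", paste(miss, collapse = ", "))
  g <- match(genes, truth$gene_id)
  if (any(!truth$expressed[g]))
    stop2("cannot assay unexpressed gene(s): ",
          paste(genes[!truth$expressed[g]], collapse = ", "))

  set.seed(seed)
  s <- ifelse(meta$line == "Ross708", 1, -1)
  t <- ifelse(meta$day == "D21", 1, -1)
  rows <- vector("list", length(g) * nrow(meta))
  k <- 0L
  for (gi in g) {
    for (j in seq_len(nrow(meta))) {
      d <- if (meta$day[j] == "D6") truth$effect_D6[gi] else truth$effect_D21[gi]
      x <- truth$lambda[gi] * 2^(s[j] * d / 2) * 2^(t[j] * truth$day_effect[gi] / 2)
      ct <- intercept - log2(x) + stats::rnorm(n_tech, 0, ct_noise_sd)
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = truth$gene_id[gi],
                              sample_id = meta$sample_id[j],
                              replicate = seq_len(n_tech), ct = ct,
                              stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  attr(plate, "normalizer") <- normalizer
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}
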