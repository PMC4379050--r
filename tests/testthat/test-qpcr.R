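make_plate <- function(ct_by_sample, n_tech = 3, jitter = 0) {
  # ct_by_sample: data.frame(gene_id, sample_id, ct)
  rows <- ct_by_sample[rep(seq_len(nrow(ct_by_sample)), each = n_tech), ]
  rows$replicate <- rep(seq_len(n_tech), nrow(ct_by_sample))
  rows$ct <- rows$ct + jitter * rep(c(-1, 0, 1), nrow(ct_by_sample))
  rownames(rows) <- NULL
  rows
}

qpcr_meta <- function() {
  data.frame(sample_id = c("R1", "R2", "I1", "I2"),
             line = rep(c("Ross708", "Illinois"), each = 2),
             day = "D6", total_mapped_reads = 1e6)
}

test_that("delta-delta Ct arithmetic and trivial cases", {
  meta <- qpcr_meta()
  wells <- expand.grid(gene_id = c("TGT", "GBAS"),
                       sample_id = meta$sample_id,
                       stringsAsFactors = FALSE)
  # Ross: target 20, GBAS 18; Illinois: target 23, GBAS 18
  wells$ct <- ifelse(wells$gene_id == "GBAS", 18,
                     ifelse(wells$sample_id %in% c("R1", "R2"), 20, 23))
  plate <- make_plate(wells)
  fc <- delta_delta(plate, meta, "TGT", "D6", normalizer = "GBAS")
  expect_equal(fc$ddct, -3)
  expect_equal(fc$fold, 8)       # Ross708-enriched, 2^3
  # equal dCt in both groups -> fold 1
  eq <- wells; eq$ct <- ifelse(eq$gene_id == "GBAS", 18, 21)
  fc1 <- delta_delta(make_plate(eq), meta, "TGT", "D6",
                     normalizer = "GBAS")
  expect_equal(fc1$ddct, 0)
  expect_equal(fc1$fold, 1)
  # efficiency-corrected fold uses base 1 + E
  fcE <- delta_delta(plate, meta, "TGT", "D6", normalizer = "GBAS",
                     efficiency = 0.9)
  expect_equal(fcE$fold, 1.9^3)
})

test_that("delta-delta Ct is invariant to a whole-plate Ct shift", {
  meta <- qpcr_meta()
  set.seed(12)
  wells <- expand.grid(gene_id = c("TGT", "GBAS"),
                       sample_id = meta$sample_id,
                       stringsAsFactors = FALSE)
  wells$ct <- runif(nrow(wells), 18, 30)
  p1 <- make_plate(wells, jitter = 0.1)
  p2 <- p1; p2$ct <- p2$ct + 5
  a <- delta_delta(p1, meta, "TGT", "D6", normalizer = "GBAS")
  b <- delta_delta(p2, meta, "TGT", "D6", normalizer = "GBAS")
  expect_equal(a$ddct, b$ddct, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # reversing the contrast inverts the fold exactly
  rev <- delta_delta(p1, meta, "TGT", "D6",
                     contrast = c("Illinois", "Ross708"),
                     normalizer = "GBAS")
  expect_equal(a$fold * rev$fold, 1, tolerance = 1e-12)
})

test_that("missing normalizer wells and replicate edge cases are handled", {
  meta <- qpcr_meta()
  wells <- expand.grid(gene_id = c("TGT", "GBAS"),
                       sample_id = meta$sample_id,
                       stringsAsFactors = FALSE)
  wells$ct <- 20
  no_norm <- wells[!(wells$gene_id == "GBAS" & wells$sample_id == "R1"), ]
  expect_error(delta_delta(make_plate(no_norm), meta, "TGT", "D6",
                           normalizer = "GBAS"), "R1")
  # single biological replicate per group: fold returned, SE/p undefined
  single <- wells[wells$sample_id %in% c("R1", "I1"), ]
  fc <- delta_delta(make_plate(single), meta, "TGT", "D6",
                    normalizer = "GBAS")
  expect_true(is.finite(fc$fold))
  expect_true(is.na(fc$se) && is.na(fc$p_value))
})

test_that("standard curves: efficiency formula and least-squares oracle", {
  q <- 10^(1:5)
  # Ct drops one cycle per doubling: slope -1/log10(2), E = 1
  ct_perfect <- 40 - log2(q)
  sc <- fit_standard_curve(q, ct_perfect)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(sc$efficiency, 1, tolerance = 1e-9)
  expect_true(sc$valid)
  # Ct drops one cycle per 10-fold: slope -1, E = 9, implausible
  expect_warning(sc9 <- fit_standard_curve(q, 40 - log10(q)), "implausible")
  expect_equal(sc9$slope, -1, tolerance = 1e-9)
  expect_equal(sc9$efficiency, 9, tolerance = 1e-9)
  expect_false(sc9$valid)
  # noisy curve vs closed-form least squares
  set.seed(3)
  ct_noisy <- 38 - 3.4 * log10(q) + rnorm(5, 0, 0.3)
  scn <- fit_standard_curve(q, ct_noisy)
  lx <- log10(q)
  slope_ref <- sum((lx - mean(lx)) * (ct_noisy - mean(ct_noisy))) /
    sum((lx - mean(lx))^2)
  expect_equal(scn$slope, slope_ref, tolerance = 1e-10)
  expect_equal(scn$intercept, mean(ct_noisy) - slope_ref * mean(lx),
               tolerance = 1e-10)
  expect_error(fit_standard_curve(c(-1, 1, 10), c(30, 28, 25)), "positive")
  expect_error(fit_standard_curve(c(1, 2, 3), c(30, 29, 28)), "log10")
})

test_that("closed loop: noise-free plates recover planted folds exactly", {
  ds <- quick_sim(n_genes = 120, frac_de = 0.1, effect_log2 = 3,
                  day_frac_de = 0, noise_free = TRUE)
  tr <- ds$truth
  targets <- tr$gene_id[tr$de_D6][1:4]
  norm <- tr$gene_id[tr$expressed & !tr$de_D6 & !tr$de_D21][1]
  plate <- simulate_qpcr(tr, ds$samples, targets, normalizer = norm,
                         ct_noise_sd = 0)
  for (g in targets) {
    fc <- delta_delta(plate, ds$samples, g, "D6")
    expect_equal(log2(fc$fold), tr$effect_D6[tr$gene_id == g],
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo plates recover the planted fold within 5%", {
  ds <- quick_sim(n_genes = 120, frac_de = 0.1, effect_log2 = 3,
                  day_frac_de = 0)
  tr <- ds$truth
  g <- tr$gene_id[tr$de_D6 & tr$effect_D6 == 3][1]
  norm <- tr$gene_id[tr$expressed & !tr$de_D6 & !tr$de_D21][1]
  folds <- vapply(1:200, function(s) {
    plate <- simulate_qpcr(tr, ds$samples, g, normalizer = norm,
                           ct_noise_sd = 0.2, seed = s)
    delta_delta(plate, ds$samples, g, "D6")$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 8) / 8, 0.05)
})

test_that("RNA-seq vs qPCR concordance: exact, sign-flipped, and noisy", {
  de_tab <- data.frame(gene_id = sprintf("g%d", 1:6), day = "D6",
                       log2_ratio = c(-2, -1, 0.5, 1, 2, 3))
  fc <- data.frame(gene_id = de_tab$gene_id, day = "D6",
                   ddct = -de_tab$log2_ratio)  # qPCR log2 fold = -ddct
  cc <- rnaseq_qpcr_concordance(de_tab, fc)
  expect_equal(cc$pearson, 1, tolerance = 1e-12)
  flipped <- fc; flipped$ddct <- -flipped$ddct
  expect_equal(rnaseq_qpcr_concordance(de_tab, flipped)$pearson, -1,
               tolerance = 1e-12)
  expect_error(rnaseq_qpcr_concordance(de_tab[1:2, ], fc[1:2, ]), ">= 3")
  expect_error(rnaseq_qpcr_concordance(de_tab,
                                       transform(fc, gene_id = paste0("x", gene_id))),
               "no genes")

  # closed loop with Ct noise: correlation matches cor() on the paired table
  ds <- quick_sim(n_genes = 200, frac_de = 0.1, effect_log2 = 2,
                  day_frac_de = 0, seed = 19)
  out <- sim_pipeline(ds)
  tr <- ds$truth
  targets <- tr$gene_id[tr$de_D6 | tr$de_D21][1:12]
  norm <- tr$gene_id[tr$expressed & !tr$de_D6 & !tr$de_D21][1]
  plate <- simulate_qpcr(tr, ds$samples, targets, normalizer = norm,
                         ct_noise_sd = 0.3, seed = 4)
  folds <- qpcr_fold_changes(plate, ds$samples)
  cc <- rnaseq_qpcr_concordance(out$de, folds)
  ref <- cor(cc$table$log2_ratio, -cc$table$ddct)
  expect_equal(cc$pearson, ref, tolerance = 1e-12)
  expect_gt(cc$pearson, 0.8)
})
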