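test_that("log2 ratios: symmetry, limit case, brute-force oracle", {
  fx <- tiny_rpkm(n_genes = 30, seed = 2)
  meta <- fx$meta
  # equal group means -> ratio 0 regardless of epsilon
  eq <- matrix(5, 4, nrow(meta),
               dimnames = list(paste0("e", 1:4), meta$sample_id))
  expect_true(all(log2_ratios(eq, meta, "D6", epsilon = 0.3) == 0))
  # 4 vs 1 with vanishing epsilon -> log2(4) = 2
  m41 <- eq
  m41[, meta$line == "Ross708"] <- 4
  m41[, meta$line == "Illinois"] <- 1
  expect_equal(unname(log2_ratios(m41, meta, "D6", epsilon = 1e-12)[1]), 2,
               tolerance = 1e-9)
  # random matrix vs scalar-loop oracle
  r <- log2_ratios(fx$rpkm, meta, "D21", epsilon = 0.01)
  for (g in rownames(fx$rpkm)) {
    mR <- mean(fx$rpkm[g, meta$sample_id[meta$line == "Ross708" &
                                           meta$day == "D21"]])
    mI <- mean(fx$rpkm[g, meta$sample_id[meta$line == "Illinois" &
                                           meta$day == "D21"]])
    expect_equal(unname(r[g]), log2((mR + 0.01) / (mI + 0.01)),
                 tolerance = 1e-12)
  }
})

test_that("per-gene Welch test agrees with stats::t.test and handles edges", {
  expect_equal(per_gene_test(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_lt(per_gene_test(c(1, 1.001, 0.999),
                          c(11, 11.001, 10.999)), 1e-4)
  set.seed(31)
  for (i in 1:40) {
    x <- rlnorm(6, 2, 1); y <- rlnorm(6, 2 + (i %% 3) / 2, 1)
    ref <- stats::t.test(log2(x + 0.01), log2(y + 0.01))$p.value
    expect_equal(per_gene_test(x, y), ref, tolerance = 1e-10)
  }
  # pluggable test function is honoured
  expect_equal(per_gene_test(1:3, 4:6, test = function(a, b) 0.123), 0.123)
})

test_that("no genes are flagged when the lines are identical", {
  meta <- tiny_meta(nrep = 3)
  set.seed(5)
  m <- matrix(NA_real_, 20, nrow(meta),
              dimnames = list(sprintf("g%02d", 1:20), meta$sample_id))
  for (day in c("D6", "D21")) {
    vals <- matrix(rlnorm(20 * 3, 2, 1), 20)
    for (line in c("Ross708", "Illinois"))
      m[, meta$sample_id[meta$day == day & meta$line == line]] <- vals
  }
  # identical replicate values in both lines -> all ratios exactly 0
  de <- suppressWarnings(call_de(m, meta, rownames(m)))
  expect_equal(nrow(de$D6$records), 0)
  expect_equal(nrow(de$D21$records), 0)
})

test_that("the 2-SD + p<0.05 rule matches an independent scalar-loop oracle", {
  ds <- quick_sim(n_genes = 200, frac_de = 0.05, effect_log2 = 3,
                  dispersion = 0.02, seed = 7)
  out <- sim_pipeline(ds)
  for (day in c("D6", "D21")) {
    # brute-force re-implementation with loops and stats::t.test
    ids_r <- ds$samples$sample_id[ds$samples$line == "Ross708" &
                                    ds$samples$day == day]
    ids_i <- ds$samples$sample_id[ds$samples$line == "Illinois" &
                                    ds$samples$day == day]
    eps <- 0.01
    flagged <- character()
    r_all <- numeric()
    for (g in out$filt$genes)
      r_all[g] <- log2((mean(out$rpkm[g, ids_r]) + eps) /
                         (mean(out$rpkm[g, ids_i]) + eps))
    rbar <- mean(r_all); sr <- sd(r_all)
    for (g in out$filt$genes) {
      p <- stats::t.test(log2(out$rpkm[g, ids_r] + eps),
                         log2(out$rpkm[g, ids_i] + eps))$p.value
      if (abs(r_all[g] - rbar) > 2 * sr && p < 0.05)
        flagged <- c(flagged, g)
    }
    expect_setequal(out$de[[day]]$records$gene_id, flagged)
    expect_equal(out$de[[day]]$r_mean, rbar, tolerance = 1e-12)
    expect_equal(out$de[[day]]$r_sd, sr, tolerance = 1e-12)
    # records sorted by |z| descending
    expect_false(is.unsorted(rev(abs(out$de[[day]]$records$z))))
    # per-line counts partition the flagged set
    expect_equal(sum(out$de[[day]]$n_enriched),
                 nrow(out$de[[day]]$records))
  }
})

test_that("swapping line labels negates ratios and swaps enrichment", {
  ds <- quick_sim(n_genes = 150, frac_de = 0.08, seed = 13)
  out <- sim_pipeline(ds)
  meta_sw <- ds$samples
  meta_sw$line <- ifelse(meta_sw$line == "Ross708", "Illinois", "Ross708")
  de_sw <- call_de(out$rpkm, meta_sw, out$filt$genes)
  for (day in c("D6", "D21")) {
    a <- out$de[[day]]$all; b <- de_sw[[day]]$all
    expect_equal(b$log2_ratio, -a$log2_ratio, tolerance = 1e-12)
    expect_setequal(out$de[[day]]$records$gene_id,
                    de_sw[[day]]$records$gene_id)
    swapped <- c(Ross708 = "Illinois", Illinois = "Ross708", none = "none")
    expect_equal(unname(swapped[a$enriched_line]), b$enriched_line)
  }
})

test_that("the flagged set is invariant to uniform RPKM rescaling", {
  ds <- quick_sim(n_genes = 150, frac_de = 0.08, seed = 17)
  out <- sim_pipeline(ds)
  scaled <- call_de(out$rpkm * 50, ds$samples, out$filt$genes,
                    de_params(epsilon = 0.01 * 50))
  for (day in c("D6", "D21"))
    expect_setequal(scaled[[day]]$records$gene_id,
                    out$de[[day]]$records$gene_id)
})

test_that("degenerate ratio SD flags nothing, with a warning", {
  meta <- tiny_meta(nrep = 2)
  # every gene shares one Ross/Illinois pattern -> constant nonzero ratios
  mm <- matrix(0, 3, nrow(meta), dimnames = list(c("a", "b", "c"),
                                                 meta$sample_id))
  mm[, meta$line == "Ross708"] <- 8
  mm[, meta$line == "Illinois"] <- 2
  expect_warning(de <- call_de(mm, meta, rownames(mm), days = "D6"),
                 "degenerate")
  expect_equal(nrow(de$D6$records), 0)
})

test_that("replicate and parameter validation", {
  fx <- tiny_rpkm(nrep = 1)
  expect_error(call_de(fx$rpkm, fx$meta, rownames(fx$rpkm)),
               ">= 2 replicates")
  expect_error(de_params(k = 0), "k")
  expect_error(de_params(alpha = 1.2), "alpha")
  expect_error(de_params(epsilon = 0), "epsilon")
})
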