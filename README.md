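# broilertx

An R package implementing a complete two-line, two-day bulk RNA-seq
comparison pipeline for chicken breast muscle: a modern commercial broiler
line (Ross708) against a legacy line (Illinois) at post-hatch days 6 and
21. It is aimed at analysts who want the published fold-change-outlier
workflow — and its qPCR verification and design-power arithmetic — as
tested, scriptable functions that run offline from a gene-level count
matrix.

## The method

Starting from counts `C_ij` (gene `i`, library `j`), gene lengths `L_i`
and per-library mapped-read totals `N_j`:

* **RPKM**: `RPKM_ij = 1e9 * C_ij / (N_j * L_i)`; a gene is *expressed*
  when its mean RPKM exceeds 0.1 in at least one (line, day) group.
* **Differential enrichment** (per day): with group means `x̄R, x̄I`, the
  statistic is `r_i = log2((x̄R + ε) / (x̄I + ε))`. A gene is flagged when
  **both** `|r_i − r̄| > 2 s_r` (mean/SD over expressed genes at that day)
  and a Welch t-test on `log2(RPKM + ε)` gives `p < 0.05`. The side of
  the mean gives the enriched line.
* **Structure**: per-day cross-line OLS concordance (slope, `R²`) and
  average-linkage hierarchical clustering of samples and of the union of
  enriched genes, on `log2(RPKM + ε)`.
* **GO-slim tallies**: annotation-instance counts per term per day from a
  local GAF/TSV map, displayed at ≥ 10 instances at either day.
* **qPCR**: ΔΔCt fold changes (`fold = 2^−ΔΔCt`, technical triplicates
  averaged first, biological samples as the unit of variance),
  standard-curve efficiency `E = 10^(−1/slope) − 1`, and RNA-seq↔qPCR
  fold-change correlation.
* **Power**: parametric negative-binomial simulation of the full design
  (`variance = μ + φμ²`), scoring end-to-end sensitivity and
  false-positive rate of the pipeline against planted truth.

A seedable synthetic-data generator (`simulate_dataset()`,
`simulate_qpcr()`) emulates the study design — 2 × 2 cells, 6 replicates,
~10M/~30M-read libraries, 15,945 genes with a 68% expressed fraction —
so every stage can be exercised and validated without any external data.

## Worked example

```r
library(broilertx)

cfg  <- sim_config(n_genes = 2000, frac_de = 0.012, effect_log2 = 2, seed = 101)
ds   <- simulate_dataset(cfg)
rpkm <- compute_rpkm(ds$counts, ds$genes, ds$samples,
                     allow_depth_below_colsum = TRUE)
filt <- filter_expressed(rpkm, ds$samples, threshold = 0.1)
de   <- call_de(rpkm, ds$samples, filt$genes)
de
#> Differential enrichment across 2 day(s)
#>   D6: 25 enriched (Ross708=12, Illinois=13), ratio mean 0.0492, SD 0.3240
#>   D21: 24 enriched (Ross708=13, Illinois=11), ratio mean -0.0413, SD 0.3224
#> Union: 48 genes

head(de$D6$records[, c("gene_id", "log2_ratio", "z", "p_value", "enriched_line")], 3)
#>   gene_id log2_ratio         z      p_value enriched_line
#> 1  G01129  -2.297341 -7.241929 5.560574e-07      Illinois
#> 2  G00306   2.358094  7.125813 7.338628e-08       Ross708
#> 3  G00990  -2.243552 -7.075926 1.983738e-07      Illinois

line_concordance(rpkm, ds$samples, "D6", genes = filt$genes)
#> D6: Illinois ~ Ross708 over 1360 genes
#>   slope 1.0119, intercept -6.0318, R^2 = 0.9064
```

Here 1,360 of 2,000 simulated genes pass the 0.1-RPKM filter; 25 genes
are enriched at D6 (12 toward Ross708, 13 toward Illinois) under the
2-SD-plus-p<0.05 rule, the strongest with ratios beyond ±2.2 log2 units
(|z| > 7); and the two lines' per-gene means agree closely (slope ≈ 1,
R² ≈ 0.91). `run_pipeline()` performs the same chain from TSV inputs and
writes `rpkm.tsv`, per-day enriched tables in the published column order,
Newick dendrograms, term tallies, qPCR folds and a `summary.json` of the
headline counters.

The design-power question is answered the same way:

```r
estimate_power(sim_config(n_genes = 1000, depths = 1e7, frac_de = 0.1,
                          effect_log2 = 2, day_frac_de = 0),
               n_sim = 50, seed = 42)
#> Power over 50 simulations (n=6/line, depth 1e+07, phi=0.05, effect 2 log2):
#>   sensitivity 0.986 (SE 0.00126), FPR 0.0000 (SE 0)
```

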