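---
title: "Methods: a two-line, two-day RNA-seq comparison pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-line, two-day RNA-seq comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilertx)
```

## The analysis this package implements

`broilertx` implements a complete, offline analysis chain for comparing
bulk RNA-seq breast-muscle transcriptomes between a modern commercial
broiler line (Ross708) and a legacy line (Illinois) at two post-hatch ages
(day 6 and day 21). The chain starts from a gene-level count matrix — read
alignment and counting are upstream and out of scope — and consists of:

1. **Quantification.** RPKM per gene and library:
   $\mathrm{RPKM}_{ij} = 10^9 \, C_{ij} / (N_j L_i)$, with $C_{ij}$ the
   read count, $N_j$ the library's total mapped reads taken from the
   sample sheet, and $L_i$ the gene length in bp. A gene is *expressed*
   when its mean RPKM strictly exceeds 0.1 in at least one (line, day)
   group.
2. **Differential enrichment.** Within each day, the per-gene statistic is
   the log2 ratio of group-mean RPKMs,
   $r_i = \log_2\!\big((\bar{x}^{R}_i + \varepsilon)/(\bar{x}^{I}_i +
   \varepsilon)\big)$. A gene is flagged when **both** (a) $|r_i - \bar r|
   > k\, s_r$, with $\bar r, s_r$ the mean and SD of the ratios across
   expressed genes at that day and $k = 2$, and (b) a per-gene two-sided
   Welch t-test on $\log_2(\mathrm{RPKM} + \varepsilon)$ gives $p < 0.05$.
   This is a fold-change-outlier rule, not a shrinkage/GLM method; it is
   implemented as published.
3. **Structure checks.** Per-day cross-line concordance (OLS of one line's
   per-gene means on the other's, with $R^2$), and hierarchical clustering
   (average linkage, Euclidean distance, heights on a distance scale) of
   samples and of the union of enriched genes on $\log_2(\mathrm{RPKM} +
   \varepsilon)$.
4. **Term tallies.** GO-slim instance counts of the enriched lists against
   a local, pre-slimmed gene-to-term map (GAF 2.x or TSV), with a
   display threshold of 10 instances at either day.
5. **qPCR arithmetic.** Delta-delta Ct relative quantification, standard-
   curve efficiency fits, and RNA-seq-vs-qPCR fold-change concordance.
6. **Power analysis.** A direct parametric simulation answering the design
   question "what fraction of truly enriched genes does this pipeline
   detect at a given replicate count and depth?".

## Decisions where the published description is silent

The published rule leaves several details open; each is an explicit,
configurable choice here:

* **Per-gene test.** No test is named for the $p < 0.05$ criterion. We use
  the Welch two-sample t-test on log2-transformed RPKM: robust to unequal
  variances, standard for 5–6 replicates per group, and pluggable
  (`de_params(test = ...)`) for anything else.
* **Ratio of means, not mean of ratios.** The supplementary table layout
  reports group-mean RPKMs next to the log2 ratio, which supports a
  means-ratio definition.
* **Pseudocount.** $\varepsilon = 0.01$ RPKM (an order of magnitude below
  the expression floor of 0.1) keeps ratios finite when one group mean is
  zero. The flagged set is invariant to a joint rescaling of RPKM and
  $\varepsilon$, so the choice of units does not leak into calls.
* **SD scope.** $\bar r$ and $s_r$ are computed over expressed genes
  (differential enrichment is only assessed post-filter);
  `sd_scope = "all"` reproduces the pre-filter alternative.
* **Multiple testing.** None by default, matching the published raw
  $p < 0.05$; Benjamini–Hochberg is available (`mtc = "BH"`).
* **Expression filter grouping.** "Expressed at > 0.1 RPKM" is read as a
  per-(line, day)-group mean criterion, since the claim is about the
  study-wide gene set; `per_sample = TRUE` gives the laxer per-library
  variant.
* **Term-count threshold.** The published methods say "> 10 instances"
  while the figure legend says "at least 10"; the default follows the
  legend (`>= 10`), and `strict = TRUE` gives the other reading.
* **Clustering.** Linkage and metric are unstated in the original; we
  default to average linkage on Euclidean distances of
  $\log_2(\mathrm{RPKM}+\varepsilon)$, rows z-standardized for the gene
  dendrogram only. Rows/columns are sorted by label first, making results
  permutation-invariant.
* **Concordance scale.** The all-gene scatter is fit on untransformed RPKM
  by default; with heavy-tailed expression the fit is dominated by the few
  most abundant genes, which is worth remembering when reading very high
  $R^2$ values. `log_scale = TRUE` fits in log space.

## What the synthetic-data generator emulates

`simulate_dataset()` reproduces the *design* of the study, so that every
stage can be exercised and scored offline against known truth:

* 2 lines × 2 days, 6 biological replicates per cell (optionally dropping
  one day-21 Illinois library, giving the study's 23-library layout);
* library depths of 1e7 reads (all day-6 libraries) with a mixed 1e7/3e7
  pattern at day 21, mirroring the study's sequencing batches;
* 15,945 annotated genes by default, of which 68% are expressed
  (10,841/15,945);
* gene lengths log-uniform on 500–10,000 bp; baseline relative abundances
  log-normal (sdlog 1.5), a heavy tail typical of muscle transcriptomes;
* per-day planted line effects on a configurable fraction of genes
  (default 1.2% per day, the order of the study's enriched-list sizes),
  split symmetrically ($\pm\delta/2$ per line) so library depth is
  preserved; a `shared_line_effects` switch makes the same genes carry the
  effect on both days, for experiments about persistent line differences;
* planted day effects (default: 20% of genes at 1 log2 unit — muscle
  transcriptomes change substantially between the two ages; these do not
  affect the within-day DE calls);
* negative-binomial counts with variance $\mu + \phi\mu^2$; $\phi = 0.05$
  by default, a typical biological-replicate dispersion for outbred birds
  at these depths; $\phi = 0$ gives Poisson and `noise_free = TRUE` gives
  rounded expected counts for closed-loop identities.

The generator does **not** model GC or length bias beyond the length term,
positional effects, unannotated transcription, or alignment artifacts.
Passing tests therefore demonstrate the correctness and calibration of the
*pipeline arithmetic* under a faithful design, not fidelity to any real
dataset: the study's own dispersion and effect-size distribution are
unknowable without re-processing the deposited data, which is out of
scope. For the same reason the published headline numbers (10,841
expressed genes, 189/193 enriched genes, $R^2$ = 0.948/0.986, the 366-gene
union) are properties of the deposited data and are not reproduction
targets for the simulator.

The matched qPCR simulator writes Ct values as
$\mathrm{Ct} = \mathrm{intercept} - \log_2(\text{relative expression}) +
\mathcal N(0, \sigma_{Ct})$ in technical triplicates, without the gene-
length term (qPCR reads out transcript concentration, not read share).

## Numerical and degenerate-input behaviour

* Welch p-values are computed vectorized over genes; rows with zero
  variance in both groups give $p = 1$ at equal means and $p = 0$
  otherwise.
* A day whose ratio SD is exactly zero flags nothing and warns (the
  outlier rule is undefined there).
* Constant rows are dropped, with a warning, before z-standardized gene
  clustering.
* Ties in dendrograms are resolved by the deterministic label sort done
  before clustering; records are ordered by $|z|$ descending with gene id
  as tie-break.
* ΔΔCt averages technical replicates within wells first; biological
  samples are the unit of variance, and the standard error combines the
  two group variances Welch-style. Groups with one biological replicate
  return a fold but `NA` uncertainty.
* Standard curves with slope ≥ 0 or efficiency outside (0, 1.1] are
  flagged invalid/implausible, not silently accepted.

## Power analysis

`estimate_power()` replaces a web-based pilot-data tool with a transparent
parametric simulation: for each replicate of the design it simulates a
dataset, runs quantification, filtering and the DE call end-to-end, and
scores sensitivity (fraction of planted genes flagged) and false-positive
rate against the planted truth. Per-simulation seeds are `seed + i` and
grid cells use `seed + 10000 * j`, so every cell is independently
reproducible. The default acceptance-scale experiment (50 simulations of
1,000 genes, 6 replicates per line, 1e7 reads, $\phi = 0.05$, 100 planted
genes per day at $|\log_2 FC| = 2$) runs in a few seconds and detects
~98% of planted genes — comfortably above the 75% design claim the
original power analysis reported for this replicate count and depth.
Under a global null ($\texttt{frac\_de} = 0$) the p-criterion false-positive
rate sits at or slightly below $\alpha$ (Welch is mildly conservative at
$n = 6$ on discrete counts), the $|z| > 2$ criterion alone flags ≈4.6% of
genes, and the conjunction flags fewer than either — the type-I behaviour
the rule's construction implies.

Problem sizes in the test suite (hundreds of genes, 10–50 simulations)
were chosen as the smallest designs at which the Monte-Carlo error is
negligible relative to the margins being asserted.

## Known limitations

* The fold-change-outlier rule is kept faithful to the original; it is
  *not* a recommended modern DE method (no variance moderation, no count
  modelling), and with many strong effects the ratio SD inflates and the
  rule loses sensitivity by construction.
* RPKM is used for fidelity, with its known between-sample comparability
  caveats; no TPM or effective-length correction is offered.
* The GO stage is a tally, not an enrichment test, matching the original
  figures; no DAG-aware slimming is performed.
* Efficiency-corrected ΔΔCt uses a single efficiency per assay from the
  standard curve; well-specific efficiency models are out of scope.
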