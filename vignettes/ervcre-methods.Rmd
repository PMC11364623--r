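---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models, the default parameters and
the deliberate numerical choices behind `ervcre`. The package analyses
chromatin-perturbation experiments in embryonic stem cells: histone
point-mutant lines in which H3.3K9 or H3.3K27 can no longer carry its
repressive methylation, leading to de-repression of ERV-derived cryptic
enhancers (K9A-like) or defective Polycomb domains at bivalent promoters
(K27A-like). Every module can be exercised end to end on data from the
built-in generator, which records its ground truth.

# The synthetic study generator

`synth_config()` holds the study design; its defaults *are* the simulated
study and are not tuned per analysis.

## Genome geometry

* 2 chromosomes of 10 Mb, binned at 250 bp. All simulated geometry (gene
  bodies, region boundaries) is **snapped to the bin grid** so that
  bin-level signal statements ("this region's mean is exactly `f_in` times
  the control") hold exactly rather than up to partial-bin proration.
* 1200 genes per genome. The gene count is scaled to the chromosome length
  so that implanted differential expression stays near a few percent of the
  transcriptome; median-of-ratios size factors assume most features are
  unchanged and become visibly biased when ~40% of genes move in one
  direction, which is a property of the estimator, not of the data.
* Three region classes (200 each): `Cluster1` (strong H3K9me3 loss,
  multiplier 0.05 in the K9A-like genotype), `Cluster2` (partial loss,
  0.5) and `nonDA` (unchanged, 1.0). Regions are placed distal to genes
  with a configurable minimum spacing.
* ERV instances are placed so that the class-wise overlap fractions are
  **realized exactly** (defaults 0.60 / 0.40 / 0.22 with a 500 bp minimum
  instance size), not merely in expectation: the acceptance checks compare
  printed percentages digit for digit, so the generator constructs the
  overlap sets combinatorially instead of sampling them.

## Signal tracks

Mean coverage surfaces are multiplicative: a background level times
region-, promoter- and genotype-specific multipliers. Noise is mean-one
lognormal (`sdlog = 0.3`), so the expected surface is preserved and
ratio-based recoveries are unbiased. Polycomb domains around SUZ12 peaks
retain a fraction `f_in = 0.7` of their H3K27me3 within the peak and
`f_flank = 0.4` in the 1.5 kb flanks in the K27A-like genotype (a
flank-biased loss); the K9A-like genotype loses H3K27me3 uniformly
(multiplier 0.75), which is the contrast the spreading analysis is built
to separate.

## Counts

Gene and TE counts are negative binomial (dispersion 0.1) with per-sample
depth factors. Genes linked to de-repressed regions receive the configured
log2 fold change (default 2) in the K9A-like genotype only; a configured
fraction of linked genes (default 0.82) is upregulated and the remainder
downregulated.

## Substream seeding

Every simulated object (one track, one count matrix, the genome itself)
draws from its own seeded stream derived by `substream_seed(root, ...)`,
a polynomial hash of the root seed and the object labels. The multiplier
is 48271 (the MINSTD Lehmer constant) modulo the Mersenne prime
2^31 - 1: every intermediate product stays below 2^53, so the hash is
exact in double precision. (An earlier draft used a FNV-style multiplier
of 16777619, whose products exceed 2^53 and silently collide.) Adding or
reordering simulated objects therefore never perturbs the others.

# Interval arithmetic

* `consensus_peaks()` keeps, by default, the **footprint** of replicate
  support: the merged extent of every replicate peak that touches a
  position covered by at least `min_support` replicates. This mirrors
  common consensus-peak practice (IDR-style pipelines keep full peak
  bodies, not just the overlapping core); `footprint = FALSE` returns the
  core instead.
* `overlap_counts()` counts each query once regardless of how many
  subjects it hits, with an optional minimum subject size (the ERV
  analyses use 500 bp).
* Printed percentages use **floor (truncation), not rounding**:
  `format_percent(1347, 2231)` is `"60%"` and
  `format_percent(1247, 8500)` is `"14%"` even though 14.67 would round
  to 15. Floor matches the way such fractions are customarily printed
  alongside their counts and guarantees the printed value never
  overstates `100 * k / n`.
* Regions are annotated by their **midpoint** with a fixed priority
  (promoter > 5' UTR > 3' UTR > exon > intron > distal), so every region
  has exactly one category and category percentages sum to 100.

# Differential testing

`differential_analysis()` normalizes with median-of-ratios size factors
(library-size fallback with a warning when no feature is positive in all
samples) and tests group differences on `log2(normalized + 1)` values:

* With fewer than 100 distinct label reassignments (e.g. 3 vs 3), a
  permutation p-value would be floored at ~1/36 and useless after FDR
  adjustment. The package instead uses **empirical-Bayes moderated
  t-statistics**: a scaled inverse-chi-square prior on the residual
  variances is fitted by moment matching on the log variances (the
  classic limma approach), the posterior variance
  `(d0*s0^2 + d*s^2) / (d0 + d)` replaces the per-feature variance, and
  the reference distribution gains the prior degrees of freedom.
  `inv_trigamma()` is solved by Newton iteration.
* With 100 or more reassignments the test enumerates (or samples) label
  permutations of a variance-moderated t-statistic and applies the
  add-one rule, so p-values are never zero and the test is exact under
  exchangeability.

TE count matrices have too few features for median-of-ratios to be
meaningful (and TE de-repression is one-directional by design), so the
pipeline passes **gene-derived size factors** to the TE contrast via the
`factors` argument.

# Region clustering

`kmeans_cluster_regions()` clusters regions on
`log2(signal + 1)`-transformed control and mutant replicate columns.
The log transform is what makes the biological structure the dominant
axis of variation: on the raw scale, within-cluster sums of squares are
dominated by overall signal magnitude, and k-means will happily split
"bright vs dim" rather than "lost vs retained". Labels are re-ordered
so that `Cluster1` is always the cluster with the lower mean
mutant/control ratio, making the naming stable across seeds.

# Bivalent promoters and spreading

`call_bivalent_promoters()` is a pure set-algebra pipeline: per-mark
consensus (>= 2 replicates) -> intersection of H3K4me3 and H3K27me3
consensus -> merge within 500 bp -> keep regions overlapping a TSS
+/- 1 kb -> optionally refine by PRC2 (SUZ12) peak overlap. Because the
definition is purely set-algebraic, the test suite checks it against an
independent per-basepair oracle on random toy genomes.

`spreading_analysis()` reports `mean(mutant)/mean(control)` of the
replicate-averaged H3K27me3 signal within each SUZ12 peak and in the
1.5 kb zones immediately up- and downstream. A flank-biased defect
(K27A-like) shows flank ratios well below the within-peak ratio; a
uniform defect (K9A-like) keeps all three zones together.

# TE enrichment by shuffling

`te_shuffle_enrichment()` compares the observed signal-region overlap of
each TE subfamily against placements re-randomized uniformly per
chromosome, with the **add-one empirical p-value**
`(1 + #{null >= observed}) / (iterations + 1)`. Two consequences are
documented rather than hidden:

* With the default 20 iterations the smallest attainable p is 1/21
  (~0.048). Claims at p < 0.01 require at least 99 iterations; the
  default favours runtime and is a floor, not a significance claim.
* The log2 enrichment adds a small pseudo-overlap to both numerator and
  denominator. At very sparse coverage this induces a Jensen-type
  negative skew of the null log2 fold change; in realistic coverage
  regimes (~10% and above) the null is centered at zero, which is what
  the acceptance suite checks.

# Enhancer-gene linkage

`candidate_pairs()` pairs regions with genes whose TSS lies within
`max_dist` (default 250 kb), signing the distance by gene strand.
`correlate_links()` computes Pearson correlations between region signal
and gene expression across shared samples (>= 4 required), converts them
to t-based p-values, adjusts by Benjamini-Hochberg and retains pairs
with `padj < fdr_cut` and, by default, `r > 0`. With few samples the
null correlation spread is wide (sd ~ 0.35 at n = 9), so the
positive-only default halves the tested family and is what makes
precision >= 0.8 achievable at FDR 0.2 on sparse genomes; negative
links can be admitted explicitly with `positive_only = FALSE`.

# Enhancer strata and ERV groups

`stratify_enhancers()` splits enhancers into weak/medium/strong at the
0.10 and 0.40 quantiles of their activity (type-7 quantiles, strict `<`
so boundary ties fall into the stronger stratum), or at absolute
boundaries on request. `classify_erv_groups()` assigns subfamilies to
three activity groups using per-mark medians as default thresholds, so
the classification is scale-free.

# Pipeline

`run_config()` validates stages and parameters against a closed list;
`run_pipeline()` runs the stage graph, fails fast when a stage's inputs
did not run, and writes every artifact as plain text plus a `report.json`
with md5 checksums and a configuration hash (the output directory is
excluded from the hash, so the same analysis in two directories hashes
identically). The CLI wrapper is installed under
`system.file("scripts", "ervcre-pipeline.R", package = "ervcre")`.
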