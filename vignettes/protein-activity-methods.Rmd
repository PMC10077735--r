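---
title: "Methods: regulon inference and protein-activity analysis of single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon inference and protein-activity analysis of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scactivity)
```

# Overview

`scactivity` infers per-cell protein activity from single-cell RNA-seq UMI
counts. Single-cell expression is sparse — most transcripts of most genes
go undetected in any given cell — so the activity of a regulatory protein
is estimated not from its own transcript but from the coordinated behavior
of its transcriptional targets (its *regulon*). The pipeline runs:

1. per-cell quality control and regularized negative-binomial
   normalization;
2. Louvain clustering in PCA space at a resolution selected by a
   correlation-distance silhouette;
3. KNN metacell pooling to mitigate dropout;
4. ARACNe-style mutual-information (MI) regulon inference with bootstrap
   consensus and data-processing-inequality (DPI) pruning;
5. aREA enrichment of each regulon in each cell's expression signature,
   integrated across networks (metaVIPER);
6. re-clustering of cells in activity space and master-regulator (MR)
   ranking per cluster by a bootstrapped t statistic;
7. bulk differential expression, GSEA of each cluster's top MRs against
   the fold-change-ranked bulk signature with leading-edge extraction, and
   per-cell GSVA pathway scores.

The package ships a synthetic-data generator with a planted regulatory
ground truth; every stage is validated by recovery of that truth rather
than by comparison with any external tool.

# The synthetic model

`generate_truth_network()` draws a gene universe whose first 20
identifiers form a mitochondrial block (`MT-` prefix, following 10x
naming), a set of regulator genes, and for each regulator a regulon of
distinct targets with a regulation sign (+1/-1) and a coupling strength.
Latent activities act log-linearly: in cluster $k$, a target's log2 mean
is

$$\log_2 \mu_g = b_g + \sum_{p \to g} s_{pg}\,w_{pg}\,a_{pk},$$

with sign $s$, strength $w$, and the regulator's own transcript tracking
its activity one-to-one. The log-linear form matches the monotone
regulator-to-target coupling that aREA assumes. Each cell adds latent
activity jitter $\varepsilon \sim N(0, \sigma_a^2)$ around its cluster's
activity ($\sigma_a = 0.5$ by default): without within-cluster variation,
all regulators active in the same cluster would have *identical* activity
profiles and no network inference method could attribute targets to the
right regulator.

Counts are drawn as a negative-binomial template (Gamma–Poisson, shared
dispersion 0.1) and then thinned multinomially to a log-normal library
size (meanlog $\log 2500$, sdlog 0.12), which gives realistic
overdispersion and dropout plus *exact* library-size control: column sums
equal the drawn library sizes. The mitochondrial block receives a
requested per-cell fraction of the thinning mass (3% by default), so
percent-mito is controlled in expectation. QC violators are planted by
rule name (`low_umi`, `high_mito`, `few_genes`, `low_complexity`).

Defaults were chosen so that a nominal cell on the desk-scale 1,000-gene
panel passes all QC rules with margin: the binding constraint is the
complexity rule $\log_{10}(\text{genes})/\log_{10}(\text{UMIs}) \ge 0.8$,
which on a small panel requires most genes to be detected in every cell;
baseline expression (log2 mean 3, sd 0.6) and the library scale were set
once to satisfy that and left alone.

What the generator does **not** emulate: batch effects beyond per-sample
library scale, doublets, ambient RNA, cell-cycle structure, or the gene-
gene correlation of real co-expression programs outside the planted
network. Passing recovery tests therefore demonstrates the machinery is
correct and calibrated, not that real tissue will yield equally clean
structure.

The bulk generator mirrors an 18-versus-20 two-group cohort; disease
log2 means shift by the planted network's response to the supplied
regulator activity changes, and the exact planted log2 fold change per
gene is returned for scoring.

# Quality control and normalization

Cells are kept iff UMIs $\ge$ 1000, detected genes within [300, 8000],
percent-mito $\le$ 5, and complexity $\ge$ 0.8, all boundaries inclusive
on the keep side. The complexity rule is implemented as the standard
metric $\log_{10}(n_\text{gene})/\log_{10}(n_\text{UMI})$; a literal
per-gene-UMI reading would discard essentially all real cells.

Normalization fits, per gene, an intercept-only negative-binomial model
with a log total-UMI offset, estimates the dispersion by maximum
likelihood (method-of-moments fallback), regularizes $\log_{10}\theta$ by
Gaussian-kernel smoothing against $\log_{10}$ gene mean (bandwidth 0.3),
and emits Pearson residuals clipped to $\pm\sqrt{n_\text{cells}}$. This
is a from-scratch regularized-NB residual scheme: its acceptance test is
parameter recovery (smoothed $\hat\theta$ within 2x of truth for >= 90%
of genes at 1,000 cells), not byte equality with any published
implementation. The 3,000 most variable genes by residual variance feed
PCA (30 components by default; an elbow detector is advisory only, since
the right count is data-dependent).

Cross-sample integration is deliberately out of scope: an optional
per-sample gene standardization (`standardize_per_sample()`, off by
default) covers location/scale batch differences, and the synthetic data
has no batch structure.

# Clustering and resolution selection

A shared-nearest-neighbor graph (Euclidean KNN, $k = 20$, Jaccard edge
weights, prune at 1/15) is clustered by Louvain modularity at each
resolution in a grid of 25 evenly spaced values in [0.01, 1.0]. Each
full-data partition is scored by the mean silhouette over 100 random cell
subsamples (min(500, n) cells each) under correlation distance
$d = 1 - r$; the resolution maximizing the mean wins, ties to the smaller
resolution. Correlation distance scores cluster separation in *profile
shape* and is invariant to per-cell affine rescaling, which suits PC
profiles. Subsampling exists because the silhouette is $O(n^2)$; 100
repeats give a stable mean with an SD the trace reports.

Markers use a one-vs-rest Wilcoxon rank-sum test (normal approximation
with tie correction) with Bonferroni correction over genes x clusters.
The rank-sum test replaces a hurdle model because it is assumption-light
and its null is exactly testable: label permutation must give uniform
p-values, and the suite asserts a false-positive rate inside
[0.02, 0.08] at $\alpha = 0.05$. Log fold changes are reported in log2 on
depth-normalized counts. Over-representation of marker lists (top 50 per
cluster by default) against user GMT collections is an upper-tail
hypergeometric test with Bonferroni correction across sets.

# Mutual information and regulon inference

Metacells are built per cluster: up to 250 seed cells, each pooling the
raw counts of its $k = 10$ nearest same-cluster neighbors in PC space
(seed included), renormalized to log2 CPM. Pooling trades single-cell
resolution for counts deep enough to estimate MI.

MI uses rank-based adaptive partitioning: the rank-rank unit square is
recursively split into quadrants at the cell midpoint, a split being
accepted when the quadrant-occupancy chi-square exceeds the 5% critical
value; accepted leaves contribute their plug-in MI term. Two numerical
choices matter and are documented here because both were found the hard
way:

* **1 df, not 3.** With rank margins, the top-level quadrant table has
  its row and column sums pinned at $n/2$, leaving one free cell: the
  correct 5% critical value is 3.84. Using the 3-df value makes the null
  MI a near-point-mass at zero and the threshold calibration degenerate.
* **Orientation canonicalization.** The midpoint split rounds odd widths
  and is not mirror-symmetric; reflecting $y$ whenever the rank
  covariance is negative makes the estimator exactly invariant to sign
  flips of either argument. Ties are broken by deterministic seeded
  jitter of magnitude $10^{-9}$ SD before ranking.

The MI significance threshold is calibrated on permutation-decoupled
expression pairs: moderate tail probabilities come from the empirical
null quantile, extreme ones (the default $p = 10^{-8}$, the conventional
ARACNe operating point) extrapolate an exponential fit of
$-\log p$ on MI over the strictly positive top-20% tail. 3,000 null pairs
are the default because the extrapolated threshold at $10^{-8}$ has
roughly 2x spread at 500 pairs and stabilizes by 3,000.

Each of 100 bootstrap iterations resamples metacells with replacement and
collapses duplicates before estimation — repeated columns would occupy
adjacent rank positions on *both* axes for every gene pair and bias MI
upward globally (the planted-network negative control exposed this).
Edges above threshold are DPI-pruned (tolerance 0: in every MI triangle
the strictly weakest edge falls, decided simultaneously against the
original edge set, which makes pruning order-independent and idempotent).
The consensus keeps edges recurring more often than the
Bonferroni-corrected ($\alpha = 0.05$) Poisson upper tail of the chance
recurrence rate. That rate is estimated from the low-count edge mass by a
smallest-fixed-point iteration: starting from sporadic edges, counts are
absorbed into the null estimate until the cut stabilizes. Estimating the
rate from the mean over *observed* edges instead (the convention at
reference scale, where false edges dominate the edge list) fails at desk
scale, where most observed edges are true and would inflate the null
rate severalfold.

Regulons take the consensus targets (capped at 50 by MI-scaled
likelihood, minimum 25 — relaxable, and the desk-scale pipeline uses 10),
with the mode of regulation as the Spearman correlation between regulator
and target across metacells. Regulator lists are user-supplied plain
text; functional classes (transcription factors, co-factors, signaling
proteins, surface markers) are run separately and unioned when supplied
as a named list. No gene-ontology queries are performed.

# aREA, metaVIPER and master regulators

Per-cell signatures are z-scores of normalized expression against the
all-cell mean and SD (a rank-normal variant is available). For a regulon
with modes $m_i \in [-1, 1]$ and likelihoods normalized to weights $w_i$,
each target contributes $s_i = m_i q_1(r_i) + (1 - |m_i|) q_2(r_i)$,
where $q_1 = \Phi^{-1}(r)$ is the directional and
$q_2 = \Phi^{-1}(0.5 + |r - 0.5|)$ the magnitude quantile of the target's
signature rank; the enrichment score $\sum_i w_i s_i$ divided by
$\sqrt{\sum_i w_i^2}$ gives a NES whose null is approximately standard
normal. The suite checks agreement with a 10,000-shuffle permutation
z-score to $|\Delta z| \le 0.15$ and null mean/SD within 0.1 of (0, 1).

metaVIPER integrates NES values across networks per protein and cell with
confidence weights $w_n = \text{NES}_n^2$:
$\sum_n w_n \text{NES}_n / \sqrt{\sum_n w_n^2}$. A protein carried by a
single network passes through unchanged — the binding contract — and the
result is invariant to network order. `min_targets` drops automatically
from 25 to 10 when the gene universe is below 2,000 genes, the desk-scale
regime.

Master regulators per activity cluster come from 100 bootstrap resamples
(cluster cells and remaining cells resampled separately) with a Welch t
per resample. The table reports both the Stouffer-style ranking statistic
$\bar t \sqrt{B} / \mathrm{sd}(t)$ — used only to order proteins — and a
p-value from the normal tail of the bootstrap-mean t. The p-value is
deliberately *not* taken from the ranking statistic: bootstrap t-values
concentrate near the observed t, so scaling their mean by $\sqrt{B}$
inflates the apparent evidence roughly tenfold and destroys type-I
control, whereas the bootstrap-smoothed t itself stays calibrated (the
suite asserts FPR in [0.02, 0.08]). "Top MRs" keep only positively
differential proteins: a protein whose activity is *depressed* in a
cluster is not a master regulator of it, and at reference scale the top
100 of thousands are all strongly positive anyway.

# Bulk arm, GSEA and GSVA

Bulk counts get TMM normalization factors (30% M-trim, 5% A-trim,
upper-quartile reference) and $\log_2(\text{CPM} + 0.5)$. Differential
expression is a simplified voom chain written in the package: precision
weights from a lowess fit of $\sqrt{\text{residual SD}}$ against mean
log2 count, a weighted two-group fit, and empirical-Bayes variance
moderation with a moment-matched prior df (trigamma inversion). Its
acceptance is statistical calibration (uniform null p, FDR control,
planted-effect sensitivity $\ge$ 0.8 at the study scale), with the
reference voom/eBayes implementation serving as an independent
cross-check in the test suite (t correlation > 0.98 observed). DEGs pass
at $|\log_2 FC| > 1$ and BH-adjusted p < 0.05; GSEA ranks the *full* gene
list by log2 fold change (a DEG-only switch exists), ties broken by |t|
then gene id.

GSEA is the weighted Kolmogorov–Smirnov walk (hit increments
$\propto |\text{metric}|^p$, $p = 1$ by default; miss decrements
$1/(N - n)$). Because the tested unit is a protein set against one fixed
ranked list, the null permutes gene sets (size-matched random draws), not
phenotypes; NES divides by the mean |ES| of sign-matched nulls and the p
is conditional on sign — using all permutations in the denominator
halves the p and breaks the null calibration. The leading edge collects
members at or before the maximum (positive ES) or at or after the
minimum. Leading-edge intersections report the overlap fraction against
each input set *and* against their union, because either denominator is
a defensible convention.

GSVA scores each cell against pathway sets: per gene a Gaussian-kernel
CDF across cells (bandwidth SD/4), per cell a KS-like walk over genes
ranked by that statistic with centered-rank weights ($\tau = 1$), scored
as max-positive plus min-negative deviation (`max_diff`; `classic` takes
the largest absolute deviation). The default input is the activity
matrix, with an expression switch. Two-group score comparisons offer
Student's t and Mann–Whitney, with an advisory Shapiro normality check
recommending the branch.

# Problem sizes and the desk-scale protocol

The standard study conditions are 1,000 genes (20 mitochondrial), 25-30
regulators with 35-40 targets each, 5 clusters of 200 cells, 800 cells
for network recovery, and an 18/20 bulk cohort — a desk-scale stand-in
for the tens of thousands of cells and four regulator classes of the
reference setting. At this scale two protocol adaptations apply, both
exposed as configuration rather than hard-coded: regulon minimum size 10
(matching the automatic aREA floor for small universes), and a single
global network context instead of per-cluster networks — 150 metacells
per cluster carry only within-cluster activity jitter, which is not
enough signal for a $p = 10^{-8}$ MI threshold, while the pooled
metacells span clusters and recover the planted regulons nearly
perfectly. At reference scale (hundreds of metacells per cluster with
rich within-cluster variation) the per-cluster default stands.

# Known limitations

* The MI estimator's absolute values are estimator-specific; only
  threshold-relative use is meaningful, which is why calibration is
  always performed against its own permutation null.
* The consensus chance-rate estimate assumes false edges recur rarely;
  heavily confounded designs (many regulators with identical activity
  profiles) violate attribution assumptions for any MI method.
* The simplified voom chain supports two-group designs only; no
  covariates, no multi-factor contrasts.
* GSVA scores are rank-based per cell; absolute score magnitudes are not
  comparable across gene sets of very different sizes.
* The bootstrapped-t MR p-values are calibrated marginally, not jointly;
  MR lists are rankings, and downstream inference runs through GSEA.
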