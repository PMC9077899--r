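---
title: "Condition-specific co-expression networks and regulatory triangle motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific co-expression networks and regulatory triangle motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgcnreg)
```

## The problem

Bulk co-expression networks built over heterogeneous sample collections
(several cohorts, healthy tissue plus tumor subtypes) wash out
relationships that exist only in a subset of the samples: a gene pair
tightly correlated in one tumor subtype but independent elsewhere shows a
mediocre global correlation and is missed. `csgcnreg` implements a
condition-specific alternative: instead of one correlation per gene pair,
the 2-D expression scatter of each pair is first decomposed into sample
clusters by a Gaussian mixture model, correlation is computed per
cluster, and clusters are statistically tied back to sample conditions.
The resulting condition-specific gene co-expression network (csGCN) is
then crossed with a tissue-specific, directed TF → target regulatory
network (tsGRN): every TF that regulates *both* endpoints of a
condition-specific edge forms a **triangle motif**, the package's unit of
a candidate regulatory-linked biomarker system. Two differential
statistics qualify the regulatory edges: per-gene differential expression
and a per-sample TF/TR expression-ratio shift.

## Pipeline and model

### Normalization and QC (`log2_quantile_normalize`, `ks_outlier_detect`)

Input matrices are genes × samples on a linear FPKM-like scale. The log2
transform maps zeros to *missing*, not to `-Inf` and not through a
pseudocount: downstream stages ignore log2 values below 0 anyway, so a
pseudocount would only manufacture an artificial point mass there.
Quantile normalization maps every sample onto the mean sorted profile;
ties share averaged ranks, and samples with unequal numbers of observed
values are matched by interpolating the reference quantile function.
Sample-level QC computes, per sample, the two-sample Kolmogorov–Smirnov
statistic against the pooled values of all *other* samples and flags
samples with D > 0.15. The reference (pooled complement rather than a
designated reference sample) is a package choice — the screening
literature uses both — and is an argument, so it can be revisited.
Flagging never removes: removal is an explicit caller decision.

### Per-pair mixture clustering (`fit_pair_gmm`)

For each gene pair, samples where either gene is missing or outside the
analyzable log2 window [0, 15] are dropped (`prefilter_values`). The
remaining 2-D points are fit with full-covariance Gaussian mixtures for
k = 1..5; k is selected by minimum BIC and samples are assigned to their
maximum-posterior component. Components with fewer than 30 members are
discarded — 30 is also the floor for a pair to be analyzed at all, since
correlation and the proportion tests below are meaningless on smaller
clusters. Fitting uses mclust's deterministic model-based hierarchical
initialisation, so the whole construction is reproducible without any
per-pair seed plumbing; this replaces the more common random-restart
k-means initialisation deliberately, trading a tiny amount of likelihood
optimality for exact determinism.

### Edge candidacy: correlation and power

Per retained cluster, the Spearman correlation must satisfy |ρ| > 0.5.
Because a cluster of 30 can reach |ρ| > 0.5 by chance more easily than a
cluster of 300, every candidate also passes a power filter based on the
Fisher z approximation,

  power = Φ(|atanh ρ| · √(n − 3) − z₀.₉₉₉₅),

requiring power ≥ 0.8 at α = 0.001 (at most 20% type-II error for the
observed effect size). At ρ = 0.5 this needs n ≈ 60; smaller clusters
must show proportionally stronger correlation.

### Condition association

A cluster is tied to a categorical condition by two one-sided proportion
z-tests (pooled variance, no continuity correction): (1) is the
condition's share *inside* the cluster higher than outside? (2) does the
cluster *capture* a higher fraction of the condition's samples than of
the other samples? Both must reject at p < 0.001. The exact form of
these two tests is not standardised in the field; the pooled one-sided
form used here is recorded and swappable. For quantitative covariates
(age, dosage, ...), a simple linear regression of the 0/1 membership
indicator on the covariate must reach r² > 0.30 with slope p < 0.001;
regressing membership on the covariate (rather than the reverse) keeps
r² identical and the slope test equivalent, so the orientation is purely
presentational.

### Bias filters

Two artifact classes are removed. *Differential cluster expression*:
both genes must shift between in-cluster and out-of-cluster samples
(Welch one-way ANOVA, p ≤ 0.001 each) — a condition label driven by only
one gene's shift, or by none, is suspect. *Missingness bias*: per gene,
the per-sample missingness indicator is compared between the labeled
condition's samples and all others with Student's t-test; p < 0.1 for
either gene drops the edge, because condition-concentrated missingness
can create a spurious condition-specific cluster. With no missing values
the edge is trivially kept. Note an inherent property of this rule:
under a perfectly *balanced* missingness null the t-test p-value is
approximately uniform, so an edge survives with probability ≈ 0.9² ≈
0.81, not ≈ 1 — the 0.1 threshold buys sensitivity to unbalanced
missingness at the price of a known false-drop rate on edges that do
carry (balanced) missingness. The test suite asserts this calibrated
band rather than pretending the filter is free.

Finally edges are ranked (stable sort by |ρ| descending, then r²
descending, then condition-test p ascending); ranking reorders, never
removes.

### Network summaries

The csGCN is undirected with unordered, deduplicated gene pairs; an edge
may carry several condition labels, which defines the condition
partition. Summaries report node/edge counts, mean degree 2E/N, and the
average local clustering coefficient with degree-<2 nodes contributing
0 — that convention (rather than excluding them) is what makes an
acyclic subnetwork report exactly ⟨C⟩ = 0, matching how published
attribute tables for such networks read. Displayed values round half
away from zero to 2 decimals. The same arithmetic is exercised against a
shipped table of published lung-network counts
(`published_network_counts()`, `derive_attribute_cells()`), where it
reproduces every derived cell.

### Differential expression and the TF/TR ratio

DE between two conditions uses a Welch t-test on log2 values with
Benjamini–Hochberg adjustment; a gene is a DEG at adjusted p < 0.001,
with an up/down direction from the sign of the log2 fold change. For
integer count matrices a per-gene negative-binomial Wald route
(`method = "nb"`) is available; the route used is recorded in the result
metadata. The package intentionally does not re-implement shrinkage
estimators — the downstream contract is only the DEG flag and direction.

The TF/TR ratio statistic takes, per sample, (TF + ε)/(TR + ε) on the
*linear* scale (ε = 0.01 guards division by zero; on the log scale a
ratio is a difference, and the scale is selectable), and compares the
two condition groups with the classical equal-variance Student's t-test
at p < 0.001, unadjusted — ratio tests are reported per edge, not
globally screened. A regulatory edge is **doubly significant** when TF
and target are both DEGs *and* the ratio shifts; the four directional
categories (TF↑TR↑, TF↓TR↓, TF↑TR↓, TF↓TR↑) partition
doubly-significant edges by construction, an invariant the tests assert
on random inputs and on the shipped published category counts
(89 + 128 + 98 + 498 = 813; 533 + 479 + 618 + 599 = 2229).

### Triangles and classification

Triangles are counted as (TF, edge) incidences: a TF appearing over k
edges contributes k motifs, and a csGCN edge regulated by m TFs
contributes m. The alternative (distinct node triples) gives the same
count unless two TFs share an edge; incidence counting is the default
because it is the unit the regulatory assessment attaches to. Extraction
is a hash join (targets → TFs) verified in tests against cubic
brute-force enumeration.

Validation asks whether a condition's triangle gene set carries enough
signal to classify samples by condition: a multilayer perceptron with
three ReLU hidden layers (512, 256, 128 units) and a softmax output,
trained with Adam (learning rate 1e-3, batch 32, L2 1e-4, 60 epochs —
all in the config and logged) on a stratified random 70% split,
evaluated as a confusion matrix on the held-out 30%. The split is
stratified per class rather than fully random: at a few hundred samples
a fully random split can orphan a class, and stratification changes
nothing else. Missing values are imputed to 0 for the classifier only
(count recorded); nowhere else in the package is anything imputed. The
MLP is implemented in plain matrix R — it is a ~200-line standard
feed-forward network, deterministic given the seed, and sized for
desk-scale gene panels.

## The synthetic study

`default_bundle()` emulates the data regime the method targets: four
conditions (two "normal", two "tumor" cohorts), 100 samples each in the
study configuration, 200 genes. On a latent log2 scale every gene is
Gaussian (means drawn in [3, 9], sd 1, keeping values inside the
analyzable window); linear values are 2^latent, so normalization is
exercised end to end. Planted structure:

* **20 condition-specific pairs** at target Spearman ρ = 0.85 via a
  Gaussian copula (Pearson ρ_p = 2·sin(πρ_s/6)), correlated *only* in
  their active condition, plus a +3 log2 mean shift for both genes
  there — the shift is what makes the cluster separable and is also the
  biological premise (condition-specific co-expression accompanies
  condition-specific expression); without it the differential-cluster-
  expression filter would, correctly, remove the edge.
* **4 TFs**, each coupled (r = 0.8) to both endpoints of one planted
  edge and to one background gene, only in that edge's condition —
  ground-truth triangles. TFs are themselves mean-shifted (±2 log2) in
  their condition, since a rewired regulator is typically differential;
  directions alternate so all four edge categories can occur.
* **14 DEGs** (log2FC ±1.5..3) in the tumor conditions, and structured
  missingness (rates 0.5/0.3) on two background genes.

What the generator does *not* emulate: library-size and GC biases,
batch effects, count-level overdispersion structure, correlated
missingness, and gene–gene correlation *networks* (only pairs and
TF fan-outs). Passing tests therefore demonstrate the statistical
machinery is correct and calibrated, not that real tumor cohorts will
yield comparable recovery.

## Problem sizes and numerical choices

The acceptance checks run the network construction over the planted
pairs plus matched null pairs (the full quadratic enumeration over 62
structured genes is the default in the analysis scripts, ~1,900 pairs);
with mixture fits at ~50 ms per pair this keeps the whole suite around a
minute while every stage still runs end to end. Further choices:

* Null calibration of the ratio test uses 10,000 replicates at n =
  100/condition — the same group size as the study fixture. In smaller
  balanced groups (n ≈ 50) the equal-variance t-test is measurably
  conservative at the 0.001 tail for skewed (log-normal) ratios.
* EM failures at some k are skipped with a warning; a pair whose fit
  fails entirely falls back to a single cluster rather than vanishing
  silently.
* Zero-variance genes never yield correlation candidates; constant
  covariates never label; a group with fewer than 2 values drops the
  edge in the Welch filter (undefined evidence is treated as failure,
  except in the missingness filter where *no missingness at all* is by
  definition balanced).
* Pair enumeration is upper-triangular with lexicographically stored
  pairs, so edge identity is order-free and output order is
  deterministic.

## Known limitations

* All-pairs construction is O(G²) mixture fits; the `genes`/`pairs`
  arguments are the provided escape hatch, not a sparsification scheme.
* The two proportion z-tests approximate; clusters barely above the
  30-sample floor with rare conditions sit at the edge of the normal
  approximation's comfort zone.
* The regulatory network is consumed as given (presence/absence);
  confidence weights pass through untouched but do not influence
  triangle extraction.
* The classifier validates *discriminative* signal of a gene set; it
  does not perform gene-set search or importance attribution.
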