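---
title: "Methods: methylation screening, gated fusion, and panel selection in oamethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation screening, gated fusion, and panel selection in oamethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oamethyl` identifies osteoarthritis-associated methylation biomarkers
and effector genes from 450K-style beta-value matrices. This vignette
documents the statistical model behind each stage, the tunable parameters
and their defaults, the design decisions taken where the methodology was
genuinely open, and what the synthetic-cohort tests do and do not
establish about real data.

## Input model and preprocessing

The unit of analysis is the beta value β ∈ [0,1], the methylation
fraction at one CpG probe in one sample. A cohort is a CpG × sample
matrix with a per-sample class label (1 = OA, 0 = control), a batch
identifier (source dataset), and optionally a joint site. Probe
annotation links each CpG to a chromosome, a 1-based coordinate, and
0–2 (gene, TSS, strand) records, following the 450K manifest convention
of 1-based closed intervals.

`harmonize_datasets()` applies the standard multi-dataset contract:
probes common to all datasets, probes with any missing value removed,
batch adjustment, precision standardization, genomic ordering. Three
choices here are ours:

* **Batch adjustment** is per-(batch, probe) mean-centering re-anchored
  to the probe's global mean. Centering then clipping to [0,1] can leave
  batch means unequal exactly where clipping bites, so the
  centering–clipping step is iterated to a fixed point (tolerance 1e-10,
  at most 50 rounds). This makes the operation idempotent — harmonizing
  an already-harmonized matrix is the identity — which the test suite
  checks bit-exactly. Location adjustment is the weakest useful model of
  a batch effect; it will not remove batch-by-probe scale effects.
* **Precision standardization** rounds half-to-even at 4 decimals
  (configurable), the typical precision of distributed beta matrices.
* **Genomic order** is the deterministic total order chr1..chr22, chrX,
  chrY, other labels lexicographically after, then position, then probe
  id, so every downstream "position" (e.g. the convolution axis of the
  classifier) is reproducible.

## Dual-strategy screening

The statistical pool uses a per-probe **Welch** (unequal-variance) two-sided
*t*-test. Welch rather than pooled-variance Student is our choice: the
motivating cohorts are strongly imbalanced (94 vs 31) and nothing
guarantees variance homogeneity between diseased and healthy tissue.
Degenerate probes (zero variance in both groups, zero difference) are
assigned t = 0, p = 1. FDR adjustment is Benjamini–Hochberg step-up via
`stats::p.adjust`; the test suite validates it against an independently
coded step-up implementation on a dense grid of 4-element vectors and
1,000 random vectors.

Probes are ranked by adjusted p ascending with |Δβ| descending as the
tie-break, then probe id; the top *k* (default 5000) form the T-pool. The
two-key ranking is stated in the source methodology without a combiner;
lexicographic (adj. p first) is the simplest faithful reading, and the
adjusted rather than raw p-value is used as the primary key because the
adjusted quantity is the one the screening criteria are expressed in.
The significance filter `significant_sites()` applies strict
inequalities, adj. p < 0.05 and |Δβ| > 0.2, exactly as printed.

The annotation pool (G-pool) takes every probe within ±2000 bp of the
TSS of a listed effector gene. "Within ±2000 bp" is read as a closed
interval: a probe at signed distance exactly −2000 is included, 2001 is
not. Distance is unsigned for membership; strand is recorded in
provenance but never used. A probe qualifying through several genes
enters once, attributed to its nearest TSS.

## Consensus feature selection

SVM-RFE uses a linear-kernel SVM (cost 1.0) on features z-scored within
the current training data, eliminating the lowest-|weight| 10% of
survivors per round (at least one; step size is our default — the source
does not state one). Random-forest ranking uses 500 trees and
mean-decrease-in-impurity importance with probe-id tie-breaks.
Permutation importance would be less biased for correlated probes but
several-fold slower; impurity is the documented default.

`cv_subset_selection()` evaluates nested top-*k* prefixes by stratified
5-fold cross-validation of the ranking's *own* model family (max-margin
for the SVM-RFE path, forest for the RF path), choosing the size with
the highest mean ACC, ties resolved by higher mean AUC, residual ties by
the smaller size. Folds are assigned on samples sorted by id, making the
result invariant to input row order. Optimal subset sizes are outputs of
this search over a configurable grid, not constants: the sizes reported
for the motivating cohorts (1100, 385, 1150) are data-specific.

T-sites and G-sites are the exact intersections of the two rankers'
optimal subsets per pool; U-sites is their union, with the cardinality
identity |A∪B| = |A| + |B| − |A∩B| asserted at construction.

## The gated Trans-CNN classifier

Each sample's beta vector x ∈ [0,1]^L becomes a token sequence: token
i = x_i·A_i + B_i + P_i with learned per-feature scale A_i, bias B_i and
position embedding P_i, all of width `d_model`. Two branches run in
parallel:

* **Attention branch**: `n_layers` Transformer encoder layers
  (multi-head self-attention, residual + layer normalization,
  ReLU feed-forward of width `ff_dim`), global average pooling over
  tokens, linear projection to `fusion_dim` → p_a.
* **Convolution branch**: stacked 1-D convolutions over the genomic
  token axis (same zero-padding, ReLU), global average pooling, linear
  projection to `fusion_dim` → p_β.

Fusion is per-dimension convex blending by a learned gate:

    Z     = [p_a ; p_β]
    g     = σ(W₂·ReLU(W₁·Z + b₁) + b₂),  g ∈ (0,1)^fusion_dim
    fused = g ⊙ p_a + (1 − g) ⊙ p_β

so every fused coordinate lies between the two branch coordinates, and
mean(g) / 1 − mean(g) summarize the branches' average contribution
weights (they sum to 1 exactly by construction). A 2-logit softmax head
closes the model; the positive-class probability comes from the softmax
and F1 is computed on the OA class.

Width defaults follow the source architecture: `d_model = cnn_out =
fusion_dim = 64`. Depth and the rest are our small-sample defaults:
2 encoder layers, 4 heads, `ff_dim` 128, kernels (7, 3) with channel
path 32→64, dropout 0.1 on the pooled branch vectors. The training
protocol (not specified in the source) is Adam at lr 1e-3 with decoupled
weight decay 1e-3 on weight matrices, minibatch 16, at most 200 epochs,
early stopping on validation accuracy with patience 20, class-weighted
cross-entropy for imbalance, inputs z-scored with training statistics.
When no explicit validation set is given a stratified 20% is held out.
Everything — forward passes, backpropagation through attention, layer
norm, convolutions and the gate, and the optimizer — is implemented in
base R; the test suite checks the analytic gradients against central
finite differences in all four fusion modes and the gate equations
against an independent scalar-loop evaluation to 1e-12.

Ablation variants (`fusion_mode`): attention-only, convolution-only,
simple concatenation, and gated fusion, trained under identical splits
and seeds for controlled comparison.

## Panel selection and provenance

Probe importance is the mean over samples of |∂(positive-class logit)/
∂x_i|, chained through the input standardization back to the beta scale;
the signed mean is available behind a flag but absolute saliency is the
default (direction is a separate question from usefulness). The panel
sweep retrains the model on each nested prefix of the importance ranking
over a size grid (default 100–320 in the source's steps), under shared
seeds and splits, and keeps the size with the best mean validation ACC,
ties to the smaller panel (parsimony). Retraining per size, rather than
reusing one model, matches the stated procedure.

Panel provenance assigns probes found in both T-sites and G-sites to the
G side (the documented policy); percentages are rounded to one decimal
and reconciled so they sum to 100.

## Gene-level analysis

Panel probes map to the union of their annotated gene symbols; probes
with no link are reported separately. Effector classification is a
three-way partition with validated-list precedence. Over-representation
uses the upper-tail hypergeometric test per gene set against a
background universe — by default every gene in the supplied annotation,
configurable because the correct universe depends on how the input gene
sets were built — with BH adjustment by the same shared routine as the
screen. Network hub scoring keeps edges with combined score ≥ 500 (a
"minimum threshold" is read as inclusive), computes degree centrality
(degree/(n−1)) and normalized betweenness (within components, pair
normalization over the whole graph), min–max standardizes each metric
over nodes (a constant metric standardizes to 0), and combines them with
equal weights 0.5/0.5 by default — no weighting was stated, and equal
weighting keeps the composite in [0,1] and neutral. Betweenness is
checked against an exhaustive shortest-path-counting oracle on random
graphs of ≤12 nodes.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` draws per-CpG baseline means from Beta(2,2), samples
individual values from a Beta distribution around the group mean with
precision 50 (within-group SD ≈ 0.07, typical of 450K probes away from
the boundaries), plants `n_dm` differential sites by shifting the case
mean by `delta_beta` (half hyper-, half hypomethylated, with headroom so
the realized group difference stays near the target after clipping),
adds mean-zero Gaussian per-(batch, CpG) location shifts (SD 0.05), and
assigns batches round-robin. Defaults mirror the motivating cohort
shape: 94 cases, 31 controls, three batches. Gene layout places genes
50 kb apart along chr1–chr22 so TSS windows never overlap, and a
configurable fraction (default 0.5) of planted sites is positioned
inside effector-gene windows.

The generator deliberately does **not** emulate probe-type (Infinium
I/II) chemistry, SNP-affected or cross-reactive probes, sex chromosomes,
correlated probe blocks (co-methylation), or cell-type composition.
Passing the planted-recovery tests therefore shows the pipeline's logic
and statistics are correct under a clean bounded-noise model, not that
effect sizes of 0.25 are detectable in any real tissue contrast.

## Problem sizes and numerical choices in the test suite

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: screening checks use
2,000-probe cohorts at n = 90 (5 seeds for recovery, 20 replicates for
the global-null false-discovery fraction); classifier checks use
10–24-feature designs at n = 120 with a 16-wide single-layer
configuration (the architecture is under test, not its capacity); the
default pipeline configuration uses a 300-probe T-pool cap, selection
grid {50, 100, 150}, sweep grid {40, 60, 80} and a 16-wide model.
All stage seeds derive deterministically from one global seed, and the
end-to-end report is fingerprinted (MD5 of its canonical JSON, timing
excluded) to assert run-to-run determinism.

Other numerical conventions: reported metrics round half-to-even at 4
decimals; rank-statistic AUC counts ties as one half; min–max
standardization of a constant vector is defined as 0; the SVM-RFE weight
vector uses |w| with probe-id tie-breaks; all RNG flows through R's
default Mersenne-Twister via explicit seeds.

## Known limitations

* Location-only batch correction; no empirical-Bayes shrinkage (ComBat-style)
  or scale adjustment.
* Impurity-based forest importance is biased toward high-entropy
  features; acceptable here because pools are homogeneous beta values.
* The from-scratch network trains on CPU at small scale; it is not a
  general-purpose deep-learning stack and large panels (thousands of
  tokens) would be slow.
* Positive-only external evaluation estimates sensitivity only; the
  object returned says so explicitly (`specificity_assessable = FALSE`).
* Hub scoring depends on the supplied interaction network's coverage;
  composite ranks are not comparable across networks with different
  score calibrations.
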