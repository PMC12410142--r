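---
title: "Marker-guided graph convolutional clustering: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-guided graph convolutional clustering: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spotgcn)
```

This vignette is the package's own account of what it computes, which
parameters matter, and where genuinely open design choices were made.

## The model

### Spatial graph

Spots on array-based platforms sit on a near-hexagonal lattice, so each
interior spot has a small set of equidistant immediate neighbors. We connect
every spot to its `k = 3` nearest other spots by Euclidean distance and
symmetrize the directed edge set by union, yielding an undirected graph whose
rows have at least `k` ones. Distance ties at the k-th neighbor — ubiquitous
on a regular lattice — resolve to the lower spot index. This makes graph
construction deterministic, at the cost of strict permutation equivariance on
tie-laden geometries (the tests permute the graph object, not the
coordinates, for exactly this reason). The propagation operator is the
symmetric normalization `S = D^-1/2 (A + I) D^-1/2`, whose spectrum lies in
`[-1, 1]`.

### Autoencoder and contrastive pre-training

The encoder is a two-layer GCN, `X -> ReLU(S X W1 + b1) -> S H W2 + b2`,
with a linear last layer so embeddings are unconstrained in sign; the decoder
mirrors it back to gene space. Layer widths default to
`n_gene -> 256 -> 64` and are configurable. The reconstruction loss is the
squared Frobenius norm of the error, *summed* (not averaged) over spots.

Contrastive learning follows the graph-infomax recipe: the positive pair is
(spot embedding, readout of its neighbor subgraph), the negative pair uses
the embedding of row-shuffled expression encoded on the *original* topology
(only features are corrupted, never edges). The readout is the elementwise
sigmoid of the mean of the neighbors' embeddings, excluding the spot itself
for consistency with the labeling walk's neighborhood convention. The
discriminator is a sigmoid bilinear form `Phi(z, g) = sigmoid(z' M g)` with
trainable `M` — it subsumes the plain dot product (`M = I`) and is the
standard choice in this family. The corrupted-view loss is the role-swapped
mirror of the original-view loss: positives `(z'_i, g'_i)`, negatives
`(z_i, g'_i)`; no asymmetric variant is described anywhere, and symmetry is
the minimal consistent reading. The total objective weighs reconstruction by
`lambda1 = 10` and both contrastive terms by `lambda2 = 1`.

All gradients are derived analytically for this fixed architecture and
verified against central finite differences in the test suite; the optimizer
is Adam (`lr = 1e-3`, no weight decay). A fresh corruption permutation is
drawn each epoch from `seed + epoch`, so runs are bit-reproducible given the
seed and BLAS. Discriminator scores are clamped to `[1e-7, 1 - 1e-7]` before
logarithms.

### Marker-gene labeling

Marker genes are first reduced to those unique to one cluster and present in
the data (a cluster losing all markers is an error; exactly one marker yields
a warning — ranking then rests on a single gene). Counts are normalized by
negative-binomial Pearson residuals with a *fixed* dispersion `theta = 100`
and clipping at `±sqrt(n_spot)`. This is a deliberately simple
variance-stabilizing transform: regularized per-gene dispersion estimation
(as in sctransform-style pipelines) is out of scope, and at `theta = 100`
the residuals are near-Poisson, which is adequate for ranking.

Spots are ranked per cluster by descending residual expression (rank-sums for
multi-marker clusters, index-order tie-breaks). The walk accepts the
top-ranked spot unconditionally, then accepts each next candidate only if the
mean PC-score vector of its graph neighbors has cosine similarity above
`0.05` with that of the **previously accepted** spot's neighbors — comparing
against a rejected spot would propagate exactly the context the rule is
meant to filter out. Each rejection increments a patience counter; a
cluster's walk ends at `patience > 10` or at the per-cluster cap
`0.3 * n_spot / n_clusters`. The patience limit and cap have no canonical
values; both defaults are exposed. The PC count defaults to 15 (a
15-versus-30 ambiguity exists in the lineage this follows; 15 is the first
figure given and is configurable). Cross-cluster collisions go to the first
cluster in map order.

### Fine-tuning, early stop, and the coverage switch

Fine-tuning retains the pre-trained weights and trains encoder *and*
classifier head (retaining weights implies further training, not freezing) by
cross-entropy on the labeled spots only. Before each epoch's update the
labeled-spot accuracy is measured; training halts at the first epoch where it
exceeds 0.9. Stopping *before* the update guarantees the returned parameters
never overshoot the threshold — important because marker-derived labels are
noisy and perfect classification of them is undesirable.

The final assignment depends on the labeled fraction `p`: below 0.20 the
classifier has too few examples to generalize, so embeddings are clustered by
a full-covariance Gaussian mixture with `K` fixed (K is known from the marker
map in every intended use; information-criterion model selection is out of
scope). At `p >= 0.20` the classifier labels all spots. The boundary
`p = 0.20` is not covered by the strict inequalities of the rule's
statement; it goes to the classifier branch, where the labeled set is at its
most informative.

The mixture is fitted by EM with `1e-6 * I` covariance regularization and
the best of 10 k-means++-seeded restarts by final log-likelihood; collapsed
components are re-seeded at a random point. The regularization means the
log-likelihood trace is monotone only up to that perturbation (the tests
allow `1e-6` relative slack).

## The synthetic benchmark

`generate_synthetic_st()` emulates the layered geometry of cortical tissue: a
triangular lattice (odd rows offset by half a spacing) partitioned into
contiguous horizontal bands, with counts drawn from a negative binomial. The
defaults — a 30 x 30 lattice, 5 bands, 2 exclusive markers per band with an
8-fold mean elevation — define the benchmark used throughout the tests. The
remaining values were chosen once as realistic for spot-level data and not
revisited: 200 genes (enough that 190 are pure noise and marker signal must
be *found*), background mean 2 counts per gene (typical per-gene UMI depth),
and NB size 2 (strong overdispersion). What the generator does **not**
emulate: irregular domain boundaries, within-domain expression gradients,
spatial covariance of library size, dropout structure beyond NB sampling,
and segmentation noise. Passing the benchmark therefore demonstrates the
machinery is correct and noise-robust in the stated regime, not that any
particular accuracy carries over to real tissue.

The label-noise protocol samples `round(p * N)` spots (rounding half away
from zero), falsifies `round(q * |sampled|)` of their labels by a uniform
draw from the other classes, and evaluates ARI only on the unsampled
complement. Replicate seeds are `base_seed + 1000 * cell_index`. Pre-training
sees neither labels nor noise, so the grid runner computes it once and shares
it across all cells — an efficiency choice with no effect on results.

## Problem sizes and numerical choices

The tests and the acceptance script run the full pipeline on the 900-spot
benchmark with a reduced training preset (150 pre-training epochs, hidden
width 64) — the loss curve has flattened by then at this scale, and the
preset keeps a complete robustness grid in the tens of seconds. The
defaults (600 epochs, width 256) remain the recommendation for real slides
with thousands of spots and 3000 HVGs.

Other numerics: HVG selection ranks genes by the variance of log-normalized
expression (the simplest reproducible dispersion statistic; any of the usual
mean-variance-trend variants could be swapped in); normalization precedes
HVG selection; library-size targets default to the median per-spot total;
zero-count spots are kept as zero rows so matrices stay aligned with the
graph; PCA signs are fixed by making each component's largest-magnitude
loading positive.

## Known limitations

- The adjacency is binary and fixed; no learned or attention-based edge
  weights.
- Full-graph training only — no mini-batching — which is fine up to tens of
  thousands of spots but not beyond.
- The marker walk labels where marker expression is strongest, a spatially
  biased sample; with `p >= 0.2` the classifier inherits that bias (the
  README's worked example quantifies it against uniformly sampled labels).
- The NB-residual normalization uses one fixed dispersion for all genes.
- `K` must be supplied (implicitly, by the marker map); the package does not
  choose the number of domains.
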