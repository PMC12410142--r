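# spotgcn

Marker-gene-guided graph convolutional clustering of spatial transcriptomics.

## The problem

Spatial transcriptomics platforms measure gene expression at thousands of
capture spots while preserving their tissue coordinates. Grouping spots into
tissue domains (e.g. cortical layers) is usually done fully unsupervised, even
though practitioners almost always *do* know something about the tissue: a
handful of marker genes per expected domain, or a few manually annotated
spots. `spotgcn` puts that domain knowledge to work while staying robust when
it is scarce or noisy.

The method has two phases:

1. **Pre-training.** Spots become nodes of a k-nearest-neighbor graph
   (k = 3 by Euclidean distance on the slide). A two-layer graph
   convolutional network (GCN) encoder maps the log-normalized,
   HVG-restricted expression matrix `X` to embeddings `Z`, with each layer
   computing `H(l+1) = sigma(D^-1/2 (A + I) D^-1/2 H(l) W(l) + b(l))`. Training
   combines a GCN-decoder reconstruction loss `L_recon = sum_i ||x_i - x^_i||^2`
   with an infomax-style contrastive loss: the embedding of a spot and the
   readout of its neighbor subgraph (sigmoid of the neighbors' mean embedding)
   form a positive pair, while embeddings of row-shuffled expression form
   negative pairs, scored by a bilinear discriminator
   `Phi(z, g) = sigmoid(z' M g)`. The total objective is
   `L = lambda1 * L_recon + lambda2 * (L_SCL + L_SCL_corrupt)` with
   `lambda1 = 10`, `lambda2 = 1`.
2. **Fine-tuning and assignment.** Sparse labels — identified from marker
   genes by a ranked, spatially-regularized walk, or supplied by the user —
   train a classifier MLP on top of the encoder with cross-entropy,
   early-stopped at the first epoch whose labeled-spot accuracy exceeds 0.9.
   The final assignment switches on the labeled fraction `p`: below 20%
   coverage the embeddings are clustered by a full-covariance Gaussian
   mixture (EM, fixed K); at or above 20% the fine-tuned classifier labels
   every spot.

A synthetic generator (triangular lattice, contiguous layered bands,
negative-binomial counts with planted marker genes) and a label-noise
simulation grid (`p` spots labeled, `q` of those labels falsified, ARI
scored on the held-out `1 - p` spots) let you quantify robustness without
any external data.

## Worked example

```r
library(spotgcn)

# synthetic slide: 30x30 lattice, 5 layered domains, 2 markers per domain
ds <- generate_synthetic_st(synthetic_config(seed = 1))
graph <- build_knn_graph(ds$coords, k = 3)

# sparse labels from the planted marker genes
lab <- identify_labels(ds, graph, attr(ds, "marker_map"))
lab
#> identified_labels: 270 of 900 spots labeled (p = 0.300), 5 cluster(s)
mean(ds$truth_labels[lab$spots] == lab$labels)
#> [1] 1

# full pipeline (small epoch preset used here)
cfg <- train_config(pretrain_epochs = 150, hidden_dim = 64, seed = 1)
res <- run_pipeline(ds, labels = lab, config = cfg)
res$report$method_used
#> [1] "classifier"
res$report$ari_vs_truth
#> [1] 0.6823477
```

The labeled coverage `p = 0.30` exceeds the 20% switch point, so the
fine-tuned classifier assigns all 900 spots. The adjusted Rand index against
the planted domains is 0.68 (1 would be a perfect recovery); marker-walk
labels concentrate where marker expression is strongest, so they train the
classifier on a spatially biased sample — uniformly sampled labels of the
same coverage, as in the simulation grid, push the held-out ARI above 0.9.
With `p < 0.20` the report would show `method_used = "gmm"` instead.

A command-line front end wrapping the same functions lives at
`inst/cli/spotgcn.R` (subcommands `run`, `identify-labels`, `simulate`,
`evaluate`; `--show-config` prints every resolved default).

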