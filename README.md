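# scgpcl

Graph prototypical contrastive learning for clustering cells in
single-cell RNA-seq count data.

Identifying cell types from an scRNA-seq count matrix is hard because
technical dropout creates excess false zeros and because the expression
differences separating cell types can be small relative to counting
noise. `scgpcl` clusters cells by learning cell representations on a
**bipartite cell–gene graph** — an edge connects a cell to each gene it
expresses, weighted by the raw count — so the relational structure of
the data is used directly instead of a precomputed cell–cell similarity
graph.

## Method

Given a raw count matrix $X^{count} \in \mathbb{N}^{N_c \times N_g}$,
cells are normalized by size factors $s_i = l_i/\mathrm{median}(l)$,
log-transformed and gene-standardized. A two-layer bipartite GraphSAGE
encoder

$$h^{(k+1)}_{c_i} = W_c' h^{(k)}_{c_i} + W_g \operatorname{Mean}_{g_j \in N(c_i)} h^{(k)}_{g_j}$$

(and symmetrically for genes) maps each cell to a latent vector. The
model is trained in two phases:

1. **Pre-training** on two stochastically augmented graph views
   (budgeted subgraph sampling + feature masking) with
   $L = \lambda_1 L_{Ins} + \lambda_2 L_{Pro} + L_{ZINB}$:
   an instance-wise InfoNCE loss over cosine similarities, a
   prototypical contrastive loss against multi-granularity k-means
   prototypes (counteracting the sampling bias of instance-wise
   negatives), and a zero-inflated negative binomial reconstruction
   likelihood $ZINB(x \mid \pi, \mu, \theta)$ decoded from the latent.
2. **Fine-tuning** by DEC-style self-training: Student's-t soft
   assignments $Q$ to trainable centroids are sharpened into a target
   $P$ ($p_{ik} \propto q_{ik}^2/f_k$) and $KL(P\|Q) + \lambda_3\,l_{ZINB}$
   is minimized until cluster labels stabilize.

The package also ships a Splat-style count simulator with logistic
dropout and ground-truth labels (`simulate_counts()`,
`simulation_case()`), clustering metrics (NMI, ARI, Hungarian-matched
accuracy, macro/micro F1; `evaluate_clustering()`), dense/MatrixMarket
IO, and a command-line interface. Everything — encoder, losses,
backpropagation, optimizer — is implemented in plain R matrix code and
validated against brute-force oracles and finite-difference gradient
checks. See `vignettes/scgpcl-methods.Rmd` for the full model
description and design choices.

## Worked example

```r
library(scgpcl)

# simulate 600 cells in 3 groups with moderate signal and dropout
cfg <- sim_config(n_cells = 600, n_genes = 1500,
                  group_probs = rep(1/3, 3), de_fac_scale = 0.5,
                  dropout_mid = 1, seed = 7)
sim <- simulate_counts(cfg)

fit <- fit_scgpcl(sim$counts, K = 3,
                  config = scgpcl_config(preset = "desk"), seed = 1)
print(fit)
evaluate_clustering(sim$labels, fit$labels)
```

```
<scgpcl_fit> 600 cells, K = 3; epochs: 8 pretrain + 2 finetune
cluster sizes:

  1   2   3
185 205 210
# A tibble: 1 × 5
    nmi   ari    ca macro_f1 micro_f1
  <dbl> <dbl> <dbl>    <dbl>    <dbl>
1 0.990 0.995 0.998    0.998    0.998
```

The fit recovers the three simulated groups almost perfectly: NMI/ARI
near 1 mean the predicted partition matches the ground-truth labels up
to relabeling, and the matched accuracy says 99.8% of cells land in the
right cluster. `tidy(fit)` returns per-cell labels with soft-assignment
confidences, `glance(fit)` a one-row run summary, and `autoplot(fit)` /
`plot_embeddings(fit)` the training curves and an embedding scatter.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/scgpcl.R", package = "scgpcl"))')
Rscript $CLI simulate --case 2 --level 0.3 --seed 0 --out sim/
Rscript $CLI fit --counts sim/counts.mtx --k 3 --out run/ --desk --seed 0
Rscript $CLI eval --pred run/labels.csv --truth sim/labels.csv
```

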