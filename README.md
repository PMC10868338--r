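# scunify

Variational integration of single-cell multi-omics data, plus a
Gaussian-process test for spatially variable genes — implemented in pure R
with hand-written backpropagation, so it runs anywhere R runs, with no deep
learning framework required.

## What it does

Single-cell experiments routinely span several batches, technologies
(scRNA-seq, scATAC-seq), or paired modalities (CITE-seq, 10x Multiome).
Non-biological batch variation dominates naive embeddings and must be removed
without erasing the cell-type signal. `scunify` provides three variational
autoencoder (VAE) integration strategies and a spatial statistics module:

- **Conditional VAE** (`fit_vipcca`): a shared encoder maps cells from all
  batches to a latent posterior `q(z | x)`; the decoder receives `[z, b]`
  where `b` is the one-hot batch code, so batch variation is absorbed by the
  decoder and `z` stays batch-free. Decoding every cell under the *reference*
  batch code yields a batch-corrected expression matrix.
- **Domain-adversarial VAE** (`fit_davae`): an unconditioned decoder plus a
  domain classifier on `z` trained with gradient reversal — the classifier
  descends its cross-entropy while the encoder ascends it, driving the latent
  space toward batch invariance.
- **Multi-view shared-latent VAE** (`fit_vimcca`): for paired assays, one
  encoder consumes the concatenated views and two decoders reconstruct each
  view from the single shared `z`, maximizing
  `E[log p(x|z)] + E[log p(y|z)] - beta * KL(q(z|x,y) || N(0,I))`.
- **Spatially variable genes** (`run_visgp`): an exact Gaussian-process
  likelihood-ratio test per gene, `y ~ N(mu, sigma2_s * K(ell) + sigma2_n I)`
  with squared-exponential kernel `K`, variance components profiled in the
  kernel eigenbasis over a lengthscale grid, boundary-corrected
  50:50 chi-squared(1) mixture p-values (or a permutation null), and
  Benjamini–Hochberg FDR control.

Supporting modules: an annotated expression container with readers/writers
for CSV, Matrix Market directories, 10x-style HDF5 and an h5ad-dialect HDF5
layout; count filtering, library-size log-normalization, highly-variable-gene
selection; kNN label transfer; synthetic data generators with planted ground
truth; and evaluation metrics (batch-mixing entropy, adjusted Rand index, kNN
accuracy). A command-line interface (`exec/scunify`) exposes the whole
pipeline.

## Quick start

The numbers below are the actual output of this code (R 4.x, single CPU,
~15 s total).

```r
library(scunify)

# simulate two batches sharing three cell types, then integrate
sim <- simulate_batches(n_cells_per_batch = c(300, 300), n_genes = 120, seed = 1)
datasets <- lapply(sim$datasets, normalize_log)

fit <- fit_davae(datasets, training_config(latent_dim = 16, epochs = 50, seed = 1))
fit
#> integration_result (davae): 600 cells, latent dim 16, 120 corrected features

batch_mixing_entropy(fit$latent, fit$batch)
#> [1] 0.9034623

clustering_ari(fit$latent, sim$truth$cell_types, n_clusters = 3)
#> [1] 0.7164238
```

Batches are locally interleaved (entropy 0.90 of a possible 1.0) while the
planted cell types remain separable (ARI 0.72 on this small problem; 0.98 at
the default 1000-cell size — see below).

```r
# spatially variable genes on a 10 x 10 lattice, 10 planted among 100
sp <- simulate_spatial(grid_side = 10, n_genes = 100, n_sv = 10, seed = 1)
res <- run_visgp(sp$sds)
head(res[, c("gene", "llr", "lengthscale", "fsv", "q")], 5)
#>        gene       llr lengthscale       fsv            q
#> 9 gene_0009 21.962145    1.000000 0.8100367 1.706632e-09
#> 3 gene_0003 18.027734    1.000000 0.7462558 4.794497e-08
#> 6 gene_0006 13.613208    1.000000 0.8094924 3.016153e-06
#> 1 gene_0001 11.459911   12.727922 0.7117794 2.111263e-05
#> 7 gene_0007  8.642689    7.231957 0.4221258 3.216525e-04

sum(res$significant)
#> [1] 8
```

All top hits are planted genes (`gene_0001`–`gene_0010` carry patterns), with
the spatial fraction of variance (`fsv`) and the profiled kernel lengthscale
reported per gene.

## Command line

```sh
scunify simulate batches --out sim/ --seed 3
scunify integrate --model vipcca --input sim/batch_0.h5ad --input sim/batch_1.h5ad \
        --out run/ --latent-dim 16 --epochs 50 --seed 1
scunify evaluate --latent run/latent.csv --truth sim/truth.json --out run/metrics.json
scunify svg --input spatial.h5ad --out svg.tsv --fdr 0.05
```

Every run writes its effective configuration (`config.yaml`) and a timestamped
`run.log` next to its outputs. Exit codes: 0 success, 2 usage error,
3 validation error, 4 numeric failure.

## Learn more

The methods vignette (`vignettes/multiomics-integration.Rmd`) derives the
three models, explains the gradient-reversal scaling and the profiled GP
likelihood, and discusses the realism and limits of the synthetic generators.
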