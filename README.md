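# scMaskClust

Clustering of single-cell RNA-seq count matrices by chaining three
stages:

1. **ZINB denoising autoencoder** — every raw count is modelled as
   zero-inflated negative binomial,
   `ZINB(x | π, μ, θ) = π δ₀(x) + (1 − π) NB(x | μ, θ)`, with per-entry
   mean `M = diag(sᵢ) exp(WμD)`, dispersion `Θ = exp(WθD)` and dropout
   probability `Π = sigmoid(WπD)` produced by three heads on a shared
   decoder. Minimising the ZINB negative log-likelihood of the raw
   counts yields a denoised matrix `X_z` (the fitted conditional mean).
2. **Masked autoencoder** — `X_z` is log1p-transformed and corrupted by
   replacing a Bernoulli-masked subset of entries
   (`M_ij ~ Bern(p_j)`, default 0.3) with within-gene shuffled values:
   `X_M = X′ ⊙ M + X_z ⊙ (1 − M)`. An encoder embeds `X_M`, a mask
   predictor estimates which entries were corrupted (binary
   cross-entropy `L_m`), and a decoder reconstructs the uncorrupted
   matrix under a mask-weighted MSE `L_rec` (weight λ = 0.7 on corrupted
   entries); the stage loss is `γ_m L_m + (1 − γ_m) L_rec` with
   γ_m = 0.65.
3. **Weighted soft K-means + KL self-training** — centres initialised by
   hard K-means on the embedding; Student-t soft assignments
   `q_ik ∝ (1 + ‖z_i − c_k‖²/t)^−(t+1)/2` (t = 1) are sharpened into a
   target `p_ik ∝ q_ik²/f_k`, and the network minimises
   `α L_zinb + β L_mask + φ L_kmeans + θ L_cluster` until labels
   stabilise. Final labels are `argmax_k q_ik`.

The package is for method developers and analysts who want a
self-contained, fully seeded implementation of this pipeline with
ground-truth simulation, ablation/sweep drivers, external metrics
(ARI, NMI, silhouette) and a command-line interface. The neural
networks are implemented in-package (dense layers, analytic
backpropagation, Adam; ZINB likelihood kernels in C++).

## Worked example

Simulate three clusters of 600 cells × 200 genes with ~45% zeros and
mean-dependent dropout, cluster, and evaluate:

```r
library(scMaskClust)

sim <- simulateCounts(simulationConfig(seed = 11))
mean(sim$counts == 0)
#> [1] 0.4436667

fit <- scMaskClust(sim$counts, nClusters = 3, config = scmcConfig(seed = 11))
fit
#> ScmcFit: 600 cells, 3 clusters, latent dim 32
#>   cluster sizes: 200, 200, 200
#>   epochs logged: 220

evaluateClustering(clusterLabels(fit), sim$labels,
                   embedding = cellEmbedding(fit))
#>   ari nmi silhouette
#> 1   1   1  0.7285677
```

`ari = 1` / `nmi = 1` mean the recovered partition matches the
generating labels exactly; the silhouette (~0.73) says the embedding
separates the clusters with wide margins. `lossHistory(fit)` holds every
loss term per epoch across the three training stages.

The same pipeline from a shell:

```sh
Rscript inst/scripts/scmaskclust.R simulate --out sim --seed 11
Rscript inst/scripts/scmaskclust.R fit --input sim/counts.tsv \
    --n-clusters 3 --out fit --seed 11
Rscript inst/scripts/scmaskclust.R evaluate --pred fit/labels.tsv \
    --truth sim/labels.tsv
```

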