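# ccan — cell cycle-aware domain separation networks for single-cell multi-omics integration

`ccan` integrates a **labeled scRNA-seq source domain** with an **unlabeled
target domain** — scRNA-seq from another protocol, or a scATAC-seq
gene-activity matrix over the same genes — while explicitly modeling the
cell cycle as a circular confounder. It transfers cell-type labels from the
source to the target, produces a joint embedding for paired (same-cell) and
unpaired designs, infers a per-cell **cell-cycle pseudotime**, and removes
the cycle's contribution from the expression matrix.

## The model

Each domain's cells×genes matrix X is split by a domain separation network
into two codes:

* a **shared (acyclic) embedding** `z_s = W3·selu(W2·selu(W1·X + b1) + b2)`,
  produced by one encoder common to both domains, carrying the
  domain-invariant cell-type signal;
* a **private (circular) embedding** `z_p = W3'·tanh(W2'·tanh(W1'·X + b1') + b2')`,
  one encoder per domain, a scalar entering the decoder only through
  `sin z_p` and `cos z_p` — so the reconstruction is 2π-periodic in `z_p`
  and `z_p mod 2π` is the cell's position on the cycle.

A shared decoder reconstructs X from
`[V_circ V_acyc]·[sin z_p; cos z_p; z_s]` followed by two linear layers, and
a softmax classifier reads cell types from the shared code only. Training
minimizes a weighted sum of

* reconstruction error `‖X_s−X̂_s‖²_F/N_s + ‖X_t−X̂_t‖²_F/N_t`,
* an orthogonality penalty `‖z_sᵀ z_p‖²_F` keeping shared and private
  factors apart,
* a multi-bandwidth Gaussian-kernel **maximum mean discrepancy** between
  the two domains' shared codes,
* cross-entropy on the labeled source, and — during refinement —
* a **cluster alignment loss**
  `(1/N_sN_t) Σ_ij [δ_ij d_ij + (1−δ_ij) max(0, m−d_ij)] + (1/K) Σ_k ‖λ_sᵏ−λ_tᵏ‖²`
  that pulls same-class source/target cells together and pushes
  different-class pairs beyond a margin, computed over class-balanced
  mini-batches.

The four-step schedule: (1) pretrain, (2) transfer labels to the target by
the classifier, (3) refine with the cluster-alignment term using those
pseudolabels (skipped in paired mode, where the true labels are shared),
(4) finalize annotations and the joint profile.

## Worked example

```r
library(ccan)

# unpaired two-modality data: labeled RNA + unlabeled gene activity,
# 4 cell types, 400 cells per domain, 100 genes, latent cycle phase
sim  <- generateMultiomics(simConfig(n_types = 4, seed = 0))
pre  <- function(d) preprocessDomain(d, scale = TRUE)
pair <- AlignedPair(pre(sourceDomain(sim$pair)), pre(targetDomain(sim$pair)))

cfg <- ccanConfig(epochs = 300, encoder_dims = c(128, 64),
                  latent_dim = 32, seed = 0)
fit <- runCcan(pair, cfg)
head(fit$annotations)
#>     cell_id predicted_label confidence
#> 1 atac_0001           type3  0.9961646
#> 2 atac_0002           type4  0.9755387
#> 3 atac_0003           type1  0.9120873
#> 4 atac_0004           type2  0.9350913
#> 5 atac_0005           type1  0.9881882
#> 6 atac_0006           type2  0.9958813
mean(fit$annotations$predicted_label == sim$truth$target_type)
#> [1] 0.87
```

`fit$annotations` holds the refined per-cell target annotation with its
softmax confidence; against the generator's ground truth the transfer is
87% accurate here (400 epochs, the package's documented transfer setting,
reaches 90–93%). `fit$joint$embedding` stacks both domains in the aligned
shared space for clustering or visualization.

For cell-cycle work use the compact preset (`ccanCycleConfig()`), then:

```r
model <- pretrainCcan(pair, ccanCycleConfig(seed = 0))
pt    <- callPhases(cyclePseudotime(model, sourceDomain(pair)))
Xcorr <- removeCycleEffect(model, sourceDomain(pair))
```

giving pseudotime in [0, 2π), G1/S/G2M calls from a three-component
Gaussian mixture, and a cycle-corrected matrix.

Evaluation helpers: `kbet()` (batch-mixing rejection rate),
`clusteringMetrics()` (RI/ARI/NMI), `classificationMetrics()`
(accuracy/macro-PRF), `separability()` (mean silhouette),
`circularCor()` (Fisher–Lee circular correlation).

A command-line front end is installed as `exec/ccan`
(`ccan simulate|pretrain|transfer|refine|embed|remove-cycle|evaluate`).

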