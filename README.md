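# gcclust — gene-cell cooperative deep clustering for scRNA-seq

Unsupervised clustering of single-cell RNA-seq data usually looks only at
the expression matrix, treating genes as anonymous feature columns. But the
genes themselves carry exogenous structure — protein–protein interactions,
shared pathways, co-regulation — that is freely available from interaction
databases and is informative about which expression patterns belong
together. `gcclust` implements a deep clustering method that injects this
exogenous gene structure into the representation-learning loop:

1. **Gene embeddings.** The dataset's highly variable genes (HVGs) are
   mapped onto an interaction-network export (STRING-style edge list) and
   embedded with node2vec: second-order biased random walks (return
   parameter *p*, in-out parameter *q*) followed by skip-gram with negative
   sampling, giving `X⁽ᵍ⁾ ∈ ℝ^{d_g × d_e}`.
2. **Cell encoder.** Cells are connected by a Pearson-correlation KNN graph
   `A⁽ᶜ⁾`; a two-layer graph attention (GAT) encoder compresses the
   log-scale HVG matrix `X⁽ᶜ⁾ ∈ ℝ^{n × d_g}` into `Z⁽ᶜ⁾ ∈ ℝ^{n × d_m}`,
   with attention coefficients
   `α_ij = softmax_j(LeakyReLU(aᵀ[W h_i ‖ W h_j]))`.
3. **Cooperative decoding.** A multilayer perceptron maps the gene
   embeddings into the same bottleneck space (`Z⁽ᵍ⁾ ∈ ℝ^{d_g × d_m}`);
   the two decoders are `Â⁽ᶜ⁾ = sigmoid(Z⁽ᶜ⁾Z⁽ᶜ⁾ᵀ)` (graph) and
   `X̂⁽ᶜ⁾ = Z⁽ᶜ⁾Z⁽ᵍ⁾ᵀ` (the gene-cell cooperative embedding).
4. **Joint objective.** `L = L_r + λ·L_c`, where
   `L_r = ‖A⁽ᶜ⁾ − Â⁽ᶜ⁾‖² + ‖X⁽ᶜ⁾ − X̂⁽ᶜ⁾‖²` (mean squared errors) and
   `L_c = KL(P‖Q)` is the deep-embedded-clustering loss built from the
   Student-t soft assignment `q_ij = (1 + ‖z_i − μ_j‖²)⁻¹ / Σ_j'(…)` and
   its sharpened target `p_ij ∝ q_ij²/Σ_i q_ij`. After a
   reconstruction-only warm-up and k-means center seeding, everything
   (network weights and centers μ) is optimized jointly with Adam; the
   final `Z⁽ᶜ⁾` is partitioned with k-means and evaluated by ARI/NMI.

Everything is implemented in plain R with analytic gradients (no deep
learning framework required), including the node2vec walk/skip-gram stack,
the full preprocessing recipe (quartile-deviation QC fences, median
library-size normalization, log2(x+1), binned-dispersion HVG selection),
and a synthetic-data generator that produces a clustered count matrix
together with a module-aligned planted-partition gene graph, so the whole
pipeline is testable offline.

## Worked example

```r
library(gcclust)

ds  <- simulate_dataset(synthetic_spec(n = 300, k = 3, d_g = 120, seed = 7))
cfg <- desk_pipeline_config(seed = 7)   # small-data profile; defaults are
                                        # pipeline_config(): 500 epochs @ 1e-5
res <- run_pipeline(ds$raw, ds$gene_edges, cfg, verbose = TRUE)
#> [gcclust] preprocess | n=274 d_g=120 seed=7
#> [gcclust] cell_graph | k=15 edges=2818
#> [gcclust] gene_embedding | d_e=32 matched=120/120
#> [gcclust] training | epochs=200 final L=810.753
#> [gcclust] evaluate | ARI=100.0% NMI=100.0%

res$metrics
#> $ari
#> [1] 1
#> $nmi
#> [1] 1

tail(res$fitres$history, 2)
#>     epoch phase      L_r      L_c  L_total ari
#> 199   199 joint 4.078610 8.083680 812.4466   1
#> 200   200 joint 4.078142 8.066745 810.7526   1
```

Reading the output: preprocessing kept 274 of 300 cells (QC fences on
library size) and all 120 genes (fewer than the default 500 HVGs);
every HVG matched the gene graph, so no fallback embeddings were needed.
`L_total = L_r + λ·L_c` with λ = 100 decreases over the joint phase, and
k-means on the refined embedding recovers the three planted clusters
exactly (ARI = NMI = 1 against the generator's labels).

Real data enter the same way: `read_expression()` for a delimited or
MatrixMarket counts matrix (+ optional labels file), and a STRING-export
edge list path in place of `ds$gene_edges`. A subcommand CLI wrapping the
same functions ships at `inst/cli/gcclust`
(`simulate | preprocess | build-cell-graph | embed-genes | train | run |
evaluate | ablate`).

`run_ablation()` reproduces the 2×2 ablation grid (gene branch on/off ×
clustering loss on/off), writing one run directory per variant with its
identity in the manifest.

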