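# icanet

Single-cell RNA-seq clustering and batch integration through independent
component analysis and protein–protein interaction (PPI) networks.

## The problem

Clustering cells from several scRNA-seq batches is confounded by two things
at once: technical batch effects that separate identical cell types, and
gene–gene co-expression that exists only in a subset of cells (so that rare
cell types vanish in global correlation analyses). `icanet` addresses both
by working at the level of *gene co-expression modules* instead of
individual genes:

1. **Decomposition.** Each batch's log-normalized expression matrix
   (log₂ CP10K) is decomposed by ICA into *expression programs* — gene-weight
   vectors **s**ₖ with zero mean and unit variance, estimated by JADE
   (deterministic, via joint diagonalization of fourth-order cumulant
   matrices) or by Icasso-stabilised FastICA. The number of components is
   chosen by random-matrix theory: the count of covariance eigenvalues above
   the Marchenko–Pastur edge (1 + √γ)², γ = min(n, p)/max(n, p).
2. **Cross-batch grouping.** Programs from all batches are pooled, compared
   by |Pearson r| over shared activated genes (|weight| > 2.5 SD), and
   clustered by PAM; the average silhouette width picks the number of
   groups, and the medoids become the *basal programs* shared across
   batches.
3. **Module detection.** A STRING-style PPI (combined score > 600) is
   weighted per basal program with w₍gh₎ = ½(ICA_g + ICA_h) where
   ICA_g = |weight of g|, zero unless both endpoints exceed 2.5 SD. Random
   walks of lengths 2–5 with the walktrap algorithm extract dense activated
   sub-networks; modules with ≥ 4 genes are pooled and de-duplicated.
4. **Scoring and clustering.** Every module is scored in every cell by the
   area under the rank-recovery curve (AUCell-style, window = top 5% of
   genes), giving a module × cell activity matrix; cells are clustered by
   Louvain on a shared-nearest-neighbor graph built in module-activity
   space.

Evaluation statistics ship with the package: ARI against cell types and
batches with F1\_ARI = 2·ARI₍ct₎(1−ARI₍b₎)/(1−ARI₍b₎+ARI₍ct₎), per-cell
LISI with its AUCDF summary and F1\_LISI, cell-type marker-module calling
(ROC AUC > 0.75, Spearman ρ ≥ 0.3, BH-corrected permutation P < 0.05),
module reproducibility by edge-weight permutation (Module Recovery Score),
and graph-signal label association y = (I + βL)⁻¹x with β = 0.8 on a
k = 30 cell kNN graph.

A synthetic-data generator (`synthetic_scenario()`, `simulate_multibatch()`,
`simulate_ppi()`) produces multi-batch counts driven by planted programs
with gene-wise batch effects, abundance-dependent dropout, a 5% rare cell
type, and a matched PPI whose dense subgraphs are the planted signatures —
so the whole method is testable offline.

## Worked example

```r
library(icanet)

sc  <- synthetic_scenario(seed = 1)        # 2 batches x 500 cells, 3 types
sim <- simulate_multibatch(sc)
net <- simulate_ppi(sc)

fit <- icanet(sim$batches, net$edges, resolution = 0.1, seed = 1)
fit
#> ICA co-expression network fit
#>   2 batch(es), 2000 variable genes, 1000 cells
#>   components per batch: 3, 3 (jade)
#>   basal programs (k_star): 4
#>   modules: 6; clusters: 3
#>   ARI cell type 1.000, ARI batch 0.001, F1_ARI 1.000

table(cluster = fit$clusters$labels, type = fit$cell_type)
#>        type
#> cluster type1 type2 type3
#>       0     0   466     0
#>       1   474     0     0
#>       2     0     0    60
```

The three planted cell types — including the 60-cell rare type — come out
as exactly three clusters, mixed across batches (ARI batch ≈ 0). The
marker-module screen ties each cluster to its planted program's module:

```r
find_celltype_modules(fit$activity, fit$clusters$labels, n_perm = 999, seed = 1)
#>     module cluster roc_auc rho     p p_adj
#> 2 module_3       0       1   1 0.001 0.001
#> 3 module_1       1       1   1 0.001 0.001
#> ...
```

`plot(fit)` draws the module × cell activity matrix ordered by cluster;
`summary(fit)` adds per-cluster composition and the full integration
report.

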