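# snproi

Three-stage association analysis between SNPs and brain regions of
interest (ROIs), for imaging-genetics researchers who want to select a
small, biologically grouped set of variants and predict continuous
imaging phenotypes from it.

Given additively coded genotypes `X` (n samples × p SNPs, codes 0/1/2) and
ROI phenotypes `Y` (n × q, e.g. FreeSurfer volume or thickness summaries),
the pipeline runs:

1. **LD-aware redundancy filtering** — agglomerative hierarchical
   clustering of pairwise SNP dissimilarities (Euclidean, absolute,
   Minkowski with any exponent r > 0, or variance-weighted), diagnosed by
   the cophenetic correlation over a 4-distance × 5-linkage grid; the tree
   is cut and each cluster's medoid SNP kept.
2. **Group-sparse multi-task feature selection** — the penalised regression

   $$\min_W \|W^\top X - Y\|_F^2 + \gamma_1 \sum_k \|W_k\|_F + \gamma_2 \sum_i \|w^i\|_2$$

   with SNP groups from genes or from LD r² ≥ 0.2 connected components,
   solved by iteratively reweighted least squares
   (`(XXᵀ + γ₁D + γ₂D̃)W = XYᵀ` with D, D̃ rebuilt from the current block
   and row norms). SNPs are ranked by row norm ‖wⁱ‖₂ and the top k kept.
3. **Support vector regression** — one ε-insensitive SVR per ROI on the
   selected SNPs (linear, polynomial or RBF kernel), evaluated with six
   error measures: MAE, RMSE, MeAE, MAPE, R², RMSPE.

A block-LD synthetic-data generator (`simulate_dataset()`) produces
cohort-scale datasets with known sparse truth, so the whole pipeline is
testable without access-restricted cohort data.

## Worked example

```r
library(snproi)

ds <- simulate_dataset(simulation_config(n_samples = 200, p_snps = 60,
                                         q_rois = 4, n_blocks = 6,
                                         n_active_groups = 2, seed = 7))
cfg <- pipeline_config(top_k = 20L, cv_folds = 3L, n_clusters = 40L)
res <- run_three_stage(ds$genotypes, ds$phenotypes, cfg)
res
#> three_stage_result: 20 feature SNPs, held-out aggregate RMSE 2.779, R2 0.5143
round(res$metrics$aggregate, 4)
#>    MAE   RMSE   MeAE   MAPE     R2  RMSPE
#> 2.2011 2.7794 1.8352 2.2014 0.5143 0.0280
mean(res$selected_snps %in% ds$active_snps)
#> [1] 0.75
```

The report says: on held-out folds the 20 selected SNPs predict the four
ROIs with an average root-mean-square error of ≈2.8 phenotype units
(baselines are ≈100, so ≈2.2% mean absolute percentage error), explain
≈51% of phenotype variance, and 15 of the 20 selected SNPs lie in truly
active LD blocks.

Stage-1 diagnostics and the multi-method comparison:

```r
scr <- linkage_distance_screen(ds$genotypes)   # 4 x 5 cophenetic grid
scr$best
cmp <- compare_methods(ds$genotypes, ds$phenotypes, cfg, k_list = c(10L, 20L))
cmp$table
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "snproi.R", package = "snproi")`) with subcommands
`simulate`, `cluster-screen`, `fit` and `compare` over delimited-text
genotype/phenotype files.

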