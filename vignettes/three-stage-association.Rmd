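---
title: "Three-stage association analysis between SNPs and brain ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage association analysis between SNPs and brain ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imaging genetics asks which genetic variants explain variation in brain
structure. The inputs are a genotype matrix $X_{n \times p}$ of additively
coded SNPs ($0$ = wild-type homozygote, $1$ = heterozygote, $2$ = mutant
homozygote) and a phenotype matrix $Y_{n \times q}$ of continuous
region-of-interest (ROI) summaries (volumes, thicknesses, densities) for the
same $n$ subjects. The goal is a small SNP set $S$ whose predictions of all
$q$ ROIs are as accurate as possible — jointly a feature-selection and a
multi-task regression problem, at dimensions (hundreds of SNPs, dozens of
ROIs, a few hundred subjects) where single-SNP testing is underpowered and
unstructured regression overfits.

`snproi` implements a three-stage pipeline:

1. **Redundancy filtering.** SNPs in strong linkage disequilibrium (LD)
   carry nearly duplicated signal. Agglomerative hierarchical clustering of
   pairwise genotype dissimilarities groups such SNPs; cutting the tree and
   keeping one representative (the medoid) per cluster removes the
   redundancy before any phenotype is consulted.
2. **Group-sparse feature selection.** A multi-task regression with a
   group penalty (G$_{2,1}$) and a row penalty ($\ell_{2,1}$) selects SNPs
   jointly across all ROIs while respecting group structure (genes or LD
   blocks).
3. **Support vector regression.** One $\varepsilon$-insensitive SVR per ROI,
   trained on the selected SNPs, provides the final predictor; kernels allow
   it to pick up non-additive genotype effects that the linear stages
   cannot.

## Stage 1: clustering and its diagnostics

Four dissimilarities between SNP columns $u, v$ over samples are supported:
Euclidean, absolute (Manhattan), Minkowski
$(\sum_i |u_i - v_i|^r)^{1/r}$, and a variance-weighted Euclidean distance
$(\sum_i (u_i - v_i)^2 / s_i^2)^{1/2}$, where $s_i^2$ is the variance of
sample $i$'s genotypes across SNPs. "Variance-weighted" is ambiguous in the
literature; we adopt the standard inverse-variance reading and document it
here prominently. The Minkowski exponent may be any $r > 0$: values below 1
(the default is $r = 0.23$, the screen's historical optimum) violate the
triangle inequality, so the result is a *power dissimilarity* rather than a
metric — agglomerative clustering only requires a dissimilarity, and
`snp_distance()` warns when $r < 1$.

Five linkage rules are available (single, complete, centroid, average,
Ward). The agglomeration itself is delegated to `stats::hclust`, the
reference implementation of the standard algorithm; its tie handling is
deterministic given the input order, which is the property that matters for
reproducibility. Centroid linkage can produce height inversions; that is
inherent to the method and left intact rather than masked.

`cophenetic_correlation()` measures how faithfully a tree represents the
input distances: the Pearson correlation between original dissimilarities
and the heights at which each pair first merges. `linkage_distance_screen()`
evaluates the full $4 \times 5$ grid and reports the combination closest
to 1. `filter_redundant()` then cuts the chosen tree into `n_clusters` flat
clusters (default $p/2$ — a deliberate, conservative halving; the
literature gives no cut rule) and retains each cluster's medoid, the member
minimising summed within-cluster dissimilarity, with ties broken towards
the lower column index.

## Stage 2: the group-sparse multi-task model

With $X \in \mathbb{R}^{d \times n}$ (SNPs standardized to zero mean, unit
variance per row) and $Y \in \mathbb{R}^{c \times n}$ (ROIs centered), the
weight matrix $W \in \mathbb{R}^{d \times c}$ minimises

$$
\min_W \; \|W^\top X - Y\|_F^2
 + \gamma_1 \sum_{k=1}^{K} \|W_k\|_F
 + \gamma_2 \sum_{i=1}^{d} \|w^i\|_2,
$$

where $W_k$ stacks the rows of SNP group $\pi_k$ and $w^i$ is row $i$.
The first penalty switches whole groups off; the second sharpens selection
inside surviving groups. Groups come from `build_groups()`: either one group
per gene symbol (unannotated SNPs become singletons) or the connected
components of the graph joining SNP pairs with LD $r^2 \ge 0.2$. Pairwise
thresholding is not transitive, so connected components (single-linkage
closure) are used to obtain a true partition.

Setting the gradient to zero gives the stationarity condition
$(XX^\top + \gamma_1 D + \gamma_2 \tilde D)\,W = XY^\top$, with $D$ block
diagonal ($1/(2\|W_k\|_F)$ for group $k$) and $\tilde D$ diagonal
($1/(2\|w^i\|_2)$). `fit_gsmurfs()` iterates the linear solve with
reweighting — iteratively reweighted least squares.

Numerical choices:

* **$\varepsilon$-floor.** $D$ and $\tilde D$ are undefined at zero norms.
  Norms are floored at $\varepsilon = 10^{-8}$ in the reweighting. With the
  floor, each sweep is an exact majorize–minimize step for the
  Huber-smoothed penalty $P_\varepsilon(t) = t$ for $t \ge \varepsilon$ and
  $(t^2 + \varepsilon^2)/(2\varepsilon)$ below, so the smoothed objective
  (returned as `objective_trace`) is guaranteed non-increasing.
* **Initialization.** $D = \tilde D = I$, making the first iterate a ridge
  solution with penalty $(\gamma_1 + \gamma_2)I$ — cheap and stable.
* **Convergence.** Iteration stops when the relative stationarity residual
  $\|XX^\top W - XY^\top + \gamma_1 D W + \gamma_2 \tilde D W\|_F /
  \|XY^\top\|_F$ falls below `tol` ($10^{-6}$ by default, `max_iter` 500).
  An objective-change rule was rejected: the objective is flat to second
  order near the optimum, so it can report "converged" while the gradient
  residual is still $\sim 10^{-3}$; the stationarity residual is the
  quantity the solution is supposed to make small, so it is also the honest
  stopping criterion.
* **Linear solve.** Cholesky factorization of the symmetric
  positive-definite system; a reciprocal-condition estimate below
  $10^{-12}$ triggers a warning.
* **Hyperparameters.** $\gamma_1 = \gamma_2 = 0.05 \max_i \|(XY^\top)^i\|_2$
  by default — a fixed fraction of the largest SNP–response cross-product
  row norm, which scales correctly with $n$ and with the phenotype units.
  Cross-validated grid search is available (and used in `fit_all_rois()`'s
  `cv_grid` for the SVR stage) but is not the default, to keep the pipeline
  deterministic and cheap.

A SNP's importance is $\|w^i\|_2$, its joint effect across ROIs;
`select_top_k()` takes the $k$ largest with ties broken towards the smaller
index. IRLS never yields exact zeros; rows below $10^{-6}$ of the maximum
row norm should be read as zero.

## Stage 3: support vector regression

Each ROI gets an independent $\varepsilon$-insensitive SVR
$f(x) = \sum_i \beta_i K(x_i, x) + b$, fitted on the selected SNPs (features
standardized inside the stage; the scale record travels with the model).
The dual is solved by libsvm via `e1071::svm`; the package stores the dual
coefficients, support vectors and bias explicitly and forms predictions
from its own kernel expansion, so the dual constraints
($\sum_i \beta_i = 0$, $|\beta_i| \le C$) are directly inspectable.

Kernel and hyperparameter defaults, all overridable: RBF kernel with
$\gamma_K = 1/(k \cdot \mathrm{Var}(X_{sel}))$; tube width
$\varepsilon = 0.1$; box constraint $C = \max(|\bar y + 3\sigma_y|,
|\bar y - 3\sigma_y|)$ (Cherkassky & Ma, 2004). The response-scaled $C$
matters: ROI phenotypes sit near 100 in typical units, and a unit box
constraint would cap the predictor at an essentially constant function. A
constant training response degenerates to predicting its mean, with a
warning.

## Evaluation

Six error measures, per ROI and aggregated by unweighted mean: MAE, RMSE,
MeAE (median of the *absolute* residuals — the definition occasionally
appears without the absolute value, which contradicts the measure's name),
MAPE, $R^2$ (not clamped; negative values are informative), and RMSPE.
Percentage measures fail loudly on near-zero truths instead of silently
skipping observations, which would bias comparisons; ROI volumes and
thicknesses are strictly positive in practice, so this is a data-validity
check rather than a restriction.

## The synthetic-data generator

Real imaging-genetics cohorts are access-restricted, so `simulate_dataset()`
provides data with the statistical structure the pipeline assumes:

* **Genotypes.** SNPs are split into LD blocks. Each block draws a latent
  exchangeable-correlation Gaussian (one shared factor, correlation
  `within_block_rho`); each coordinate is thresholded at the Hardy–Weinberg
  quantiles of a per-SNP minor allele frequency drawn from `maf_range`,
  giving genotype frequencies $(1-m)^2, 2m(1-m), m^2$. Blocks are
  independent.
* **Effects.** `n_active_groups` blocks carry i.i.d. normal weights on all
  ROIs; all other rows of the true weight matrix are exactly zero.
* **Phenotypes.** `baseline + signal + noise`, with per-ROI baselines
  $\sim U(80, 120)$ (keeping phenotypes positive, like real ROI summaries)
  and noise scaled so that per-ROI $\mathrm{Var(signal)/Var(noise)}$ equals
  `snr`. The quadratic link adds a centered squared-genotype term with the
  same sparsity pattern — a component invisible to any additive linear
  model, giving the SVR stage a regime in which nonlinearity genuinely
  matters.

Defaults mirror the motivating cohort's scale — $n = 632$, $p = 486$,
$q = 56$ — with 40 LD blocks, $\rho = 0.7$ (typical intra-block LD),
MAF $\in (0.05, 0.5)$, 4 active blocks, SNR 5 and a linear link. These were
fixed once, as plausible cohort-like conditions, and are not tuned.

What the generator does **not** emulate: population stratification and
relatedness, realistic LD decay within blocks (exchangeable correlation is
flat), genotyping missingness patterns, covariate effects (age, sex, ICV),
and spatially correlated imaging noise across ROIs. Tests passing on this
generator therefore certify the algorithmic contracts — optimality,
recovery under the assumed structure, calibration — not performance on any
real cohort.

## The pipeline and the method comparison

`run_three_stage()` executes filter → group → fit → select → SVR inside
each of `cv_folds` seeded sample-level folds (all stages refit per training
fold; stage 1 touches only genotypes, but refitting it per fold keeps the
protocol uniform) and reports held-out metrics, plus a final full-data fit
for the published SNP set and models. `compare_methods()` runs ordinary
least squares, ridge, the group-sparse model as a direct linear predictor,
and both three-stage variants (gene- vs LD-grouping) on identical folds
across a grid of $k$. `headline_comparison()` is a single-split (80/20)
variant cheap enough to repeat over many seeds; the test suite uses it on
quadratic-link data at the default scale, where the three-stage pipeline
beats ridge in the large majority of seeds and its error varies less over
$k \in \{20, \dots, 100\}$ than the group-sparse linear readout's — the
stability property that motivates placing an SVR, rather than the sparse
model itself, at the readout stage.

Problem sizes in the test suite were chosen to exercise each property at
the smallest scale where it is meaningful: oracle comparisons at
$d, n \le 30$, recovery at $n = 500, p = 200$ over 20 seeds, and the
headline comparison at the full $632 \times 486 \times 56$ scale over 20
seeds.

## Known limitations

* The redundancy filter's cut depth and the medoid rule are pragmatic
  defaults; no claim of optimality is made for them.
* Covariate adjustment is out of scope; residualize phenotypes beforehand
  if needed.
* The LD-grouping threshold ($r^2 \ge 0.2$) is a field convention, not a
  fitted quantity; on weakly structured data it can produce one giant
  component, in which case gene-based grouping is preferable.
* IRLS returns numerically small rather than exactly zero rows; use the
  documented $10^{-6}$ relative threshold when reporting support.
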