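# sugsclust

Fast approximate Bayesian clustering with variable selection for
high-dimensional continuous data — expression matrices, proteomic panels and
similar standardised omics tables where the number of clusters is unknown
and most variables may carry no clustering signal.

## What it does

`sugsclust` implements sequential updating and greedy search (SUGS) inference
for Dirichlet-process Gaussian mixture models. Observations
$x_1,\dots,x_n \in \mathbb{R}^D$ follow a DP mixture with concentration
$\beta$ and conjugate Normal–Gamma base measure, variables independent given
the allocation. Each observation is allocated greedily to the cluster
maximising

$$P(z_i = k \mid x_{1:i}, z_{1:i-1}) \propto
  \sum_l \phi_l^{(i-1)} \, \pi_{ikl} \, L_{ik}(x_i),$$

where $\pi_{ikl}$ is the Chinese-restaurant prior weight
($n_k$ or $\beta_l$, over $\beta_l + i - 1$) at grid value $\beta_l$,
$\phi^{(i-1)}$ the sequentially updated grid posterior over $\beta$, and
$L_{ik}$ the Student-$t$ posterior-predictive density of cluster $k$. One
pass is deterministic given an ordering; many random orderings are scored by
marginal likelihood (ML) or pseudo-marginal likelihood (PML).

On top of plain SUGS the package provides:

* **Variable selection** (`sugs_varsel()`): binary relevance indicators
  $\gamma_d$ distinguish cluster-specific from globally distributed
  variables; clustering passes alternate with greedy per-variable posterior
  updates, multi-started from random variable sub-samples.
* **Bayesian model averaging**: the scored model ensemble is reduced by
  Occam's window, and co-clustering matrices and masks are averaged into a
  posterior co-clustering matrix, per-variable selection scores, and an
  average-linkage consensus partition.
* **Simulators, metrics and a pipeline**: the benchmark Gaussian-mixture
  generators (`simulate_mixture()`, `scenario_preset()`), adjusted Rand
  index and variable-recovery metrics, and `run_pipeline()`, which writes a
  complete plain-text result bundle with full provenance.

The sequential pass is in C++ (Rcpp); a full analysis of a 100 × 200 matrix
(600 candidate models) takes a few seconds.

## Worked example

Simulate the flagship benchmark — 100 observations from a 3-component
mixture (weights 0.5/0.3/0.2, means 0/±2 on relevant dimensions), 200
variables of which half are pure noise — then cluster with variable
selection:

```r
library(sugsclust)

sim <- simulate_mixture(n = 100, D = 200, relevant_fraction = 0.5, seed = 11)
set.seed(11)
fit <- sugs_varsel(sim$X, subsample_fraction = 0.1, n_subsamples = 20,
                   orderings = 30)
fit
#> Greedy DP clustering with variable selection
#>   n = 100 observations, D = 200 variables, 600 models explored
#>   best model (ML): 3 clusters, 103 variables selected
#>   Occam's window: 6 of 21 distinct models retained
#>   consensus partition: 3 clusters

evaluate_clustering(fit$allocations, sim$labels, fit$mask, sim$mask)
#> Adjusted Rand index: 1.0000
#> Relevant variables recovered:   1.0000
#> Irrelevant variables excluded:  0.9700
```

The three components are recovered exactly (ARI 1), all 100 relevant
variables are selected, and 97% of the noise variables are excluded.
`summary(fit)` tabulates the ensemble; `plot(fit)` draws the model-averaged
co-clustering heatmap; `fit$variable_scores` gives each variable's posterior
selection probability; `predict(fit, newX)` allocates new observations.

Plain clustering without variable selection (`sugs()`, PML selection) works
well when most variables are informative but collapses when few are — the
motivating contrast for the variable-selection extension:

```r
set.seed(1)
sugs(sim$X, orderings = 30)$n_clusters        # 3 on 50%-relevant data
sugs(scenario_preset("table4", seed = 11)$X,
     orderings = 30)$n_clusters               # 1 on 5%-relevant data
```

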