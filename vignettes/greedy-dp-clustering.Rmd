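---
title: "Greedy sequential clustering and variable selection in DP Gaussian mixtures"
author: "sugsclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy sequential clustering and variable selection in DP Gaussian mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugsclust)
```

## The model

`sugsclust` performs fast approximate Bayesian inference in Dirichlet-process
(DP) Gaussian mixture models. Observations $x_1, \dots, x_n \in \mathbb{R}^D$
are modelled as draws from a mixture whose mixing measure has a DP prior with
concentration $\beta > 0$ and conjugate Normal–Gamma base measure. Integrating
out the mixing measure yields the Chinese-restaurant conditional prior for the
cluster label $z_i$ given the previous labels: an occupied cluster $k$ with
$n_k$ members is chosen with probability proportional to $n_k$, a new cluster
with probability proportional to $\beta$ (both normalised by $\beta + i - 1$).

Variables are assumed independent given the cluster allocation (diagonal
covariance), so each (cluster, dimension) pair carries its own
Normal–Gamma posterior over a mean and precision,
$\tau \sim \mathrm{Gamma}(a, b)$,
$\mu \mid \tau \sim N(m, (c\tau)^{-1})$, and all predictive densities and
marginal likelihoods are available in closed form (Student-$t$ predictives
with $2a$ degrees of freedom and squared scale $b(c+1)/(ac)$).

## The greedy sequential pass

Rather than MCMC, the fitting algorithm visits the observations once, in a
given order, and allocates each to the cluster maximising its posterior
allocation probability — the product of the CRP prior weight and the
cluster's current posterior-predictive density — with the concentration
parameter marginalised over a discrete grid whose weights are updated
sequentially as allocations are made. Allocations are never revised, so one
pass costs $O(nKD)$ Student-$t$ evaluations; the pass is implemented in C++
(`src/sugs_pass.cpp`), with a pure-R reference implementation that the test
suite checks against it. Ties in the argmax go to the lowest cluster label,
making each pass fully deterministic given its inputs.

The result depends on the visiting order, so `sugs()` repeats the pass over
random orderings and selects one finished partition by a model-selection
criterion: by default the pseudo-marginal likelihood (PML), the product of
leave-one-out predictive densities, because the marginal likelihood (ML) is
known to favour partitions with many small clusters. The PML uses the
full-data posterior as an approximation to the leave-one-out posterior
(accurate to $O(1/n)$); an exact leave-one-out mode exists
(`log_pseudo_marginal(..., exact = TRUE)`) and is verified against a
brute-force refit oracle in the tests.

## Variable selection

For high-dimensional data, each variable $d$ carries a binary relevance
indicator $\gamma_d$: relevant variables follow cluster-specific
distributions, irrelevant ones a single global distribution shared by all
observations. Given a partition, the posterior odds of $\gamma_d$ compare the
clustered evidence of column $d$ (product of per-cluster Normal–Gamma
evidences) with its global single-component evidence, times the prior
$p_0(\gamma_d = 1)$; indicators are set greedily and independently per
variable, with exact ties resolved towards inclusion. `sugsvarsel_fit()`
alternates a fresh clustering pass given the current mask with a greedy
indicator update given the new partition, for `iterations = 2` rounds by
default (further rounds rarely change the result in this design and double
the cost).

Because the alternation depends on both the ordering and the initial mask,
`sugs_varsel()` uses a random sub-sampling initialisation: a fraction
(default 10%) of the variables is drawn, the alternating fit is run on the
sub-matrix over a small number of orderings (10 by default) with all
indicators on, the best sub-run by sub-matrix ML is extended to a full-length
mask by one greedy update over all $D$ variables, and the whole procedure is
repeated for `n_subsamples` draws. Each resulting mask seeds alternating fits
under `orderings` fresh random orderings, giving a
`n_subsamples * orderings` model ensemble scored by marginal likelihood.

Two structural choices were genuinely open and are resolved as follows. The
concentration-grid posterior restarts at its prior in every alternation
round: each round is a complete fresh pass, so carrying the grid posterior
over would double-count the data. In the initialisation phase, model
selection among the orderings uses the ML of the sub-matrix (the quantity
actually available before extension); the full-dimension ML is only computed
after the mask has been extended. If a greedy update switches every variable
off (possible on pure-noise data with a small inclusion prior), the previous
mask is kept and alternation stops; if a sub-sample's extension is all-off,
the sub-sampled variables themselves are switched on.

## Model averaging

Every fitted model is a (partition, mask) pair with a marginal likelihood.
Besides selecting the single best model (Bayesian model selection), the
ensemble is summarised by Bayesian model averaging: models are weighted by
their posterior probability under a uniform model prior (a log-sum-exp
softmax of the log evidences), duplicate (partition, mask) pairs arising from
different orderings are collapsed to one copy first (the posterior weights
distinct models, and the number of orderings that happen to reach a model
should not bias the average; `dedup = FALSE` restores keep-all behaviour),
and models outside Occam's window — posterior weight more than `occam_ratio`
(default 100, the upper end of the conventional 20–100 range) below the best
— are discarded and the remaining weights renormalised.

The windowed models' binary co-clustering matrices (entry 1 when two
observations share a cluster; invariant to relabelling) are averaged with
these weights into the model-averaged co-clustering matrix, whose entries are
posterior co-clustering probabilities, and the masks are averaged likewise
into per-variable selection scores. A consensus partition is obtained by
average-linkage hierarchical clustering on one minus the averaged matrix,
cut by default at dissimilarity 0.5 (majority co-clustering) or at a fixed
`consensus_k`; the cut rule is a package choice, as is enforcing exact
monotonicity of the merge heights (average linkage is reducible, so heights
are monotone up to floating-point round-off, which the height cut must not
trip over). On data violating the diagonal-covariance assumption, the
consensus is measurably more accurate than the single best model; the test
suite checks this property over 20 simulated replicates.

## Prior defaults

The per-dimension Normal–Gamma prior defaults to $m = 0$, $c = 1$, $a = 1$,
$b = 1$: a unit-information prior for standardised data — one
pseudo-observation at the origin, prior mean precision 1, prior predictive a
Student-$t_2$ with squared scale 2. Two failure modes motivated this choice
and are worth knowing about.

* A much smaller $c$ (say $0.01$) with $b/a = 1$ gives a prior predictive
  with per-dimension scale $\approx 10$ on standardised data. In more than a
  few dozen dimensions the new-cluster option then loses to any occupied
  cluster by hundreds of nats and every pass returns a single cluster.
* Matching the prior predictive scale tightly to the data (e.g. $a = 3$,
  $b = 1.5$) removes the per-dimension entry cost of new clusters entirely
  and the pass shatters the data into dozens of clusters.

The heavy-tailed unit-information compromise reproduces the expected
behaviour across the package's benchmark scenarios. One residual effect
remains at large $n$ with few relevant variables: the marginal likelihood's
per-cluster Occam factor, $\tfrac12 \log\{c/(c+n_k)\}$ per dimension, is
comparatively weak at $c = 1$, so max-ML selection can prefer a moderately
over-split model even when the ensemble contains the true structure; the
model-averaged consensus is the more robust summary there. The concentration
grid defaults to 30 points log-uniform on $[0.01, 100]$ with a uniform
prior, wide enough to bracket both few- and many-cluster regimes; the
inclusion prior defaults to $p_0(\gamma_d = 1) = 0.5$ per variable
(uninformative; at 0.5 the mask prior is constant across masks and selection
reduces to pure data evidence).

## The synthetic benchmarks

`simulate_mixture()` generates the benchmark designs used throughout the
tests: a three-component Gaussian mixture with proportions
$(0.5, 0.3, 0.2)$, component means $0$, $2$ and $-2$ on every relevant
dimension, identity covariance, and irrelevant columns i.i.d. standard
normal; component membership is multinomial, so realised proportions
fluctuate at small $n$. Presets `table1`–`table4` fix $n = 100$, $D = 200$
with 50/25/10/5% relevant variables, `table5`–`table7` fix $n = 1000$,
$D = 100$ with 25/10/5% relevant. `simulate_correlated_example()` generates
the small ($n = 30$) design with one deliberately correlated component
(covariance 2 on the diagonal, 1 off it) that violates the independence
assumption, plus two noise columns — the setting where model averaging beats
model selection. Simulated columns are already near mean 0, variance 1, so
the presets are analysed unstandardised; `read_matrix(standardise = TRUE)`
standardises user data.

What these generators do *not* emulate: correlated noise, heavy-tailed or
skewed measurement error, batch structure, and missing values. Passing the
benchmark suite therefore demonstrates correct inference under the model's
own assumptions (plus one controlled violation), not robustness on arbitrary
real data.

The acceptance script (`scripts/acceptance.R`) and the heavy test block use
10 replicate datasets per scenario with the protocols the benchmarks define:
30 orderings and 20 sub-samples for the $n = 100$ scenarios, 10 and 10 for
the $n = 1000$ scenarios, 2 alternation rounds, max-ML selection for
variable selection and max-PML for plain clustering. These sizes keep a full
run in the minutes range on one CPU while leaving the Monte-Carlo error of a
median over 10 replicates at a few hundredths of ARI.

## Numerical choices

All probability computation is in log space; normalisations use max-shifted
log-sum-exp. Sufficient statistics (per-cluster counts, means, centred sums
of squares) are accumulated by `rowsum`/`tabulate`, with a non-negativity
clamp on round-off. Within-pass per-cluster state caches $\sum_d \log b_d$
so a candidate evaluation costs one `log1p` per mask-on dimension.
Determinism contracts: identical inputs give bit-identical allocations; all
randomness (orderings, sub-samples) is drawn from the session RNG before any
parallel dispatch, so results are independent of the worker count.

## Limitations

Greedy sequential allocation never revisits an assignment, so early mistakes
persist; the multi-start ensemble mitigates but does not eliminate this, and
order dependence is intrinsic. Marginal-likelihood selection can over-split
(see above). The diagonal-covariance assumption makes correlated relevant
variables look like extra structure; a single global component is assumed
for all irrelevant variables; and the alternation has no ascent guarantee —
the package asserts only that the reported model maximises the ensemble's
score. Non-conjugate likelihoods and per-cluster variable selection are out
of scope.
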