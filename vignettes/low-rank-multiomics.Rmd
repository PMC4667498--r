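---
title: "Integrative low-rank dimension reduction and clustering of multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative low-rank dimension reduction and clustering of multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lromics)
```

## The problem

Molecular subtyping of tumor cohorts (and similar stratification problems in
other tissues) draws on several omics layers at once: continuous measurements
such as DNA methylation or copy number, binary somatic mutation indicators,
and sequencing counts. The layers live on different scales and follow
different noise models, yet the biological signal that separates subtypes is
believed to be shared and low-dimensional — a handful of pathway-level
factors drives many correlated features across all layers. `lromics`
estimates that shared subspace directly and clusters samples inside it.

## The model

Each data block $X^{(k)}$ (features of one type in rows, the common samples
in columns) is modeled entry-wise, conditionally independently given a
size-matched matrix of natural parameters $\Theta^{(k)}$:

* **gaussian** (real-valued data): $X_{ij} \sim N(\Theta_{ij}, 1)$, minus
  log-likelihood $\tfrac12 (X_{ij}-\Theta_{ij})^2$;
* **binary** (0/1 data): $X_{ij} \sim \mathrm{Bernoulli}(\sigma(\Theta_{ij}))$
  with the logistic $\sigma$, minus log-likelihood
  $-[X_{ij}\Theta_{ij} - \ln(1+e^{\Theta_{ij}})]$;
* **poisson** (counts): $X_{ij} \sim \mathrm{Poisson}(e^{\Theta_{ij}})$,
  minus log-likelihood $-(X_{ij}\Theta_{ij} - e^{\Theta_{ij}})$ with
  $\ln X_{ij}!$ dropped.

Categorical features are dummy-coded into full one-hot binary rows
(`dummy_encode()`); no reference level is dropped, so all levels are treated
symmetrically by the low-rank prior. Normalization constants are dropped
throughout; every derived quantity that compares likelihoods (notably the
explained-variation statistic) uses the same convention and is therefore
invariant to it.

The per-block parameter matrices stack into one matrix $\Theta$, and the
shared-low-dimensional-signal assumption becomes a nuclear-norm penalty on
the stack:

$$\hat\Theta = \arg\min_\Theta \; L(\Theta) + \mu\,\|\Theta\|_*$$

where $L$ is the summed minus log-likelihood over all blocks and
$\|\cdot\|_*$ is the sum of singular values, the convex surrogate for rank.
Both $L$ (each per-type term has non-negative second derivative in
$\Theta_{ij}$) and the penalty are convex, so the problem has a global
optimum and no restarts are needed.

## The algorithm

`lra_fit()` uses singular value thresholding: starting from $\Theta = 0$,
it alternates

1. a gradient step $\Theta \leftarrow \Theta - \delta \nabla L(\Theta)$
   with fixed step length $\delta$ (default 0.5), and
2. the shrinkage $\Theta \leftarrow U D_\mu(\Sigma) V^T$, where
   $\Theta = U \Sigma V^T$ and $D_\mu$ maps each singular value $\lambda$ to
   $\max(\lambda - \mu, 0)$ — the proximal operator of $\mu\|\cdot\|_*$.

Rather than asking the user for the penalty weight $\mu$, the solver takes
the target rank $r$ (the dimension of the reduced subspace) and re-chooses
$\mu$ **each iteration** as the $(r+1)$-th largest singular value of the
post-gradient-step matrix. The shrinkage then retains at most $r$ singular
values while perturbing them as little as possible, so the iterate has rank
at most $r$ by construction at every iteration (`rank_trace` records this).
When fewer than $r+1$ singular values exist, $\mu = 0$. If
$\sigma_r = \sigma_{r+1}$ exactly, the rule is applied verbatim and the
shrunken rank falls below $r$; we document rather than "fix" this tie
behavior, since it is measure-zero under noise.

**Convergence.** Iterations stop when the relative change of the penalized
objective falls below `tol` (default `1e-6`) or after `max_iter` (default
100) iterations. On the package's default synthetic conditions the solver
converges in roughly 40–50 iterations; the objective decreases monotonically
after the first couple of iterations (the per-iteration re-selection of
$\mu$ can cause a tiny initial wobble), and the explained-variation and
$\mu$ traces flatten within a few iterations.

**Step length and curvature.** The classical guarantee for this scheme —
any step in $[0.5, 2]$ converges — is derived for quadratic (gaussian) loss,
whose curvature is exactly 1. The binary loss has curvature at most $1/4$
and is harmless; the Poisson loss has curvature $e^{\Theta_{ij}}$, so a
fixed step $\delta$ is contractive only while
$\delta \cdot \max_{ij} e^{\Theta_{ij}} < 2$. With $\delta = 0.5$ that means
Poisson rates must stay below 4, or the iteration can enter a small
period-two oscillation around the optimum instead of settling. This is a
real limitation of the fixed-step scheme for count data with large means:
for such data, pre-scaling counts, a smaller step (at the cost of a warning,
since it leaves the documented range), or a variance-stabilizing transform
to the gaussian model are the practical options. The synthetic generator
is calibrated to respect this bound (below).

**SVD strategy.** A full LAPACK SVD is computed each iteration. At the
problem sizes this package targets in its tests and examples (hundreds to a
few thousand features, tens to hundreds of samples) the SVD is not the
bottleneck; the cost grows with $\min(p, n)^2 \max(p, n)$, and
features-by-samples omics matrices keep $\min(p,n) = n$ moderate.

## Choosing the rank: explained variation

Let $\mathcal{L}_r^*$ be the (constant-dropped) log-likelihood of the
rank-$r$ fit, $\mathcal{L}_0^*$ its value at $\Theta = 0$ (rank-zero
anchor, `null_loglik()`), and $\mathcal{L}_\infty^*$ the saturated optimum
(`saturated_loglik()`, available in closed form per type: 0 for gaussian and
binary, $\sum_x x\ln x - x$ for poisson). The explained variation

$$\mathrm{EV}(r) = 1 - \frac{\mathcal{L}_\infty^* - \mathcal{L}_r^*}
{\mathcal{L}_\infty^* - \mathcal{L}_0^*} \in [0, 1]$$

is 0 for the rank-zero model and approaches 1 at saturation. `scan_rank()`
traces $\mathrm{EV}(r)$ over candidate ranks; the curve is non-decreasing
(a larger $r$ is a weaker constraint) and on data with a genuine low-rank
signal it rises steeply up to the intrinsic rank and then flattens.
`elbow_rank()` locates the maximum drop in slope (with the rank-0 anchor
prepended); visual inspection of the curve is just as valid, and the package
deliberately imposes no automatic choice inside the pipeline unless the user
leaves the rank unset. A degenerate denominator (saturated equal to null,
i.e. constant data) is defined as EV = 1.

## Reduction and clustering

For the fitted $\Theta = U\Sigma V^T$ with rank at most $r$, the $r$ leading
components of $\Sigma V^T$ give each sample an $r$-vector of coordinates on
the top singular directions — the integrated low-dimensional representation
(`reduce_dims()`). On gaussian-only, row-centered input this subspace
coincides with classical PCA of the data matrix (the fit's optimum is a
soft-thresholded truncated SVD of $X$): the test suite asserts principal
angles below $10^{-3}$ rad against the PCA subspace, and component-wise
correlations of scores above 0.999. Each coordinate row's
largest-magnitude entry is made non-negative — SVD signs are arbitrary, and
a fixed convention makes runs and plots reproducible.

`cluster_samples()` runs Lloyd's k-means in the reduced space, with
k-means++ seeding and 20 restarts by default (best total within-cluster sum
of squares kept), deterministic under the recorded seed. The number of
clusters is chosen by the mean silhouette value, $(b-a)/\max(a,b)$ averaged
over samples (Euclidean distance in the reduced space; singleton clusters
score 0 by Rousseeuw's convention; degenerate all-coincident geometry is
defined as silhouette 0 with a warning). `scan_clusters()` reports the curve
and the argmax.

`signature_features()` describes clusters post hoc: each feature is tested
between one cluster and the rest (Wilcoxon rank-sum for gaussian and count
features, a two-proportion chi-squared test for binary features) with
Benjamini–Hochberg correction across all features of all blocks. The choice
of tests is a pragmatic, distribution-light default — the clustering itself
does not depend on them. P-values are descriptive, not selective-inference
corrected: the clusters were found on the same data.

## The synthetic generator

`simulate_multiomics()` draws data from the model's own generative
assumptions, which is exactly what makes it a sharp test of the estimator:

* cluster centers at the vertices of a regular simplex in the
  $r$-dimensional latent space, pairwise `separation` apart, under a random
  rotation (random rescaled centers when $k - 1 > r$);
* sample factors = own center + gaussian noise with standard deviation
  `latent_sd` (default 0.5, so the default separation of 4 places centers 8
  within-cluster standard deviations apart — planted clusters are
  recoverable essentially without error, which is the regime the recovery
  tests are meant to exercise; at `latent_sd = 1` the Bayes error at
  separation 4 is already ≈3%, and no method can exceed ARI ≈ 0.9);
* per-block loadings i.i.d. gaussian (`theta_scale`), so the planted
  $\Theta$ has rank exactly $r$;
* binary rows rescaled so 99% of success probabilities lie in
  $[0.05, 0.95]$; Poisson rows rescaled so **all** rates lie in $[1/3, 3]$ —
  the hard cap keeps $\delta \cdot \max e^\Theta = 1.5 < 2$, inside the
  fixed-step solver's contraction region (see above);
* observations drawn per type: additive $N(0, \texttt{noise\_scale}^2)$
  noise, Bernoulli draws, Poisson draws; optional uniform missingness
  masks entries (masked entries contribute zero likelihood and gradient).

Default conditions: 90 samples, 3 clusters, rank 2, blocks of 200 gaussian,
100 binary and 150 poisson features, separation 4. The generator seeds its
parameter draw and its observation draw from the stored seed, so datasets
are bit-for-bit reproducible, and `write_simulation()` stores the spec and
true labels alongside the matrices.

What the generator does **not** emulate: real methylation beta-value
bimodality, mutation sparsity patterns, overdispersed counts, batch
structure, or feature-feature correlation beyond the planted low-rank
signal. Passing the recovery tests therefore shows that the estimator and
pipeline are correct under the model's assumptions — it does not certify
performance on real cohorts, where rank selection and cluster number are
empirical judgments on the EV and silhouette curves.

## Numerical choices and degenerate inputs

* $\ln(1 + e^\theta)$ is computed in the log1p-exp stable form; $e^\theta$
  is clipped at $\theta = 50$ with a warning (a guard, not an operating
  regime — the shrinkage keeps parameters moderate).
* Anchors satisfy $-L(0) = \mathcal{L}_0^*$ exactly and
  $-L(\Theta) \le \mathcal{L}_\infty^*$ for all $\Theta$; tiny numeric
  excursions of EV outside $[0,1]$ are clipped.
* `rank` may equal $\min(p, n)$, in which case $\mu = 0$ and the fit is
  unconstrained (an unconstrained gaussian fit reproduces $X$ to $10^{-6}$).
* Gaussian features are used as supplied (unit-variance model); optional
  per-feature centering/standardization (`center`, `scale.`) is off by
  default, so the user decides whether scale differences between features
  are signal or nuisance.
* Missing entries: supported everywhere via the observation mask
  (standard marginalization for conditionally independent entries);
  `NA` cells in input files become masked entries.
* Sample alignment across blocks defaults to `strict` (identical sample
  sets required); `intersect` subsets to the common samples and logs what
  was dropped.

## Problem sizes

The test suite and the acceptance script run the default 450 x 90 stacked
problem (five seeds), smaller 130 x 45 variants, a 100/500/1000-feature
scaling family, and the PCA-equivalence fits at 100 x 60; the full suite
completes in well under a minute on one CPU. These sizes were chosen so
every property is exercised at a scale where the full-SVD solver is fast;
nothing in the implementation is specific to them.

## Known limitations

* Fixed step length: count data with large means violate the contraction
  condition (see above); the solver reports non-convergence honestly via
  the `converged` flag and the objective trace.
* The gaussian model fixes variance 1 for all features; features with very
  different scales should be standardized beforehand if that is not
  intended.
* No sparsity on loadings: every feature loads on every latent direction;
  feature selection is the user's pre-processing responsibility.
* k-means assumes roughly isotropic clusters in the reduced space; any
  other clusterer can be run on `reduce_dims()` output instead.
* Negative-binomial (overdispersed) counts are not modeled.
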