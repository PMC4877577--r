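---
title: "Methods: geographically weighted logistic lasso and coverage indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographically weighted logistic lasso and coverage indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwlasso)
```

## The model

`gwlasso()` fits a spatially varying coefficient model for a binary
areal outcome.  At every calibration location $i$ the outcome follows a
local logistic regression, $\mathrm{logit}\,\mu_j = \beta_{i0} +
x_j^\top \beta_i$, estimated from *all* $N$ units with Gaussian
distance-decay weights $w_{ij} = \exp\{-\tfrac12 (d_{ij}/\theta)^2\}$.
Because the model has $N(p+1)$ coefficients for $N$ observations it is
unidentifiable without the kernel: the weights tie each local fit to
its spatial neighbourhood, and the bandwidth $\theta$ controls how
local that neighbourhood is (as $\theta \to \infty$ all weights
approach 1 and every local fit collapses to the single global logistic
regression — a property the test suite asserts to $10^{-5}$).

Each local fit solves

$$\min_{\beta_{i0},\,\beta_i}\;
  \sum_j \tilde w_{ij}\,\ell(y_j, \eta_j)
  \;+\; \lambda\Big[\alpha \lVert\beta_i\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta_i\rVert_2^2\Big],$$

where $\ell$ is the binomial negative log-likelihood contribution,
$\tilde w$ are the kernel weights normalized to sum one, and the
intercept is unpenalized.  With $\alpha = 1$ (the default) this is the
lasso: locally irrelevant coefficients are set to exactly zero, so the
*set* of selected covariates varies over the map.  $\alpha < 1$ gives
the elastic net, useful when covariates are strongly collinear and the
lasso's arbitrary within-group selection is undesirable.

Two conventions deserve explicit statement because they change the
numerical value of the hyperparameters:

* **Kernel form.**  We use the GWR-standard half-exponent Gaussian
  kernel $\exp\{-\tfrac12 (d/\theta)^2\}$.  The alternative
  $\exp\{-(d/\theta)^2\}$ (available via `form = "gaussian-squared"`)
  is the same family with $\theta$ rescaled by $\sqrt2$; any bandwidth
  selected by cross-validation is convention-consistent, so the choice
  does not affect fitted probabilities, only the reported $\hat\theta$.
* **Loss normalization.**  The local loss is divided by the total
  kernel mass $\sum_j w_{ij}$.  Without this, the effective scale of
  $\lambda$ would depend on how much kernel mass a location happens to
  have (edge locations see less), and a single CV-selected $\lambda$
  would penalize different locations by different amounts.  A
  sum-parameterized shrinkage translates as
  $\lambda_{\text{sum}} = \lambda_{\text{gwlasso}} \cdot \sum_j w_{ij}$.
  One practical consequence: the solution is invariant to rescaling all
  weights by a positive constant (tested).

## The inner solver

The penalized weighted logistic fits are computed by cyclic coordinate
descent on the iteratively reweighted least squares (IRLS) quadratic
approximation, compiled via Rcpp — the same architecture as glmnet,
re-authored here because the weight-normalized local objective is the
heart of the method.  Details that matter numerically:

* warm starts along a descending $\lambda$ path, so a whole path costs
  little more than one fit; the path starts from the exact null model
  ($\beta = 0$, intercept at the weighted-logit mean), which makes the
  all-zero solution at $\lambda \ge \lambda_{\max}$ *exact*, not
  approximate;
* $\lambda_{\max} = \max_k |\sum_j \tilde w_j x_{jk}(y_j - \bar p_w)|$
  (divided by $\max(\alpha, 10^{-3})$ for the elastic net) anchors
  automatic grids: geometric over three decades, glmnet-style, computed
  at the kernel row with the greatest total mass;
* convergence when the largest coefficient change falls below $10^{-8}$
  (inner) with an outer IRLS loop that re-evaluates the true objective
  and *backtracks by step-halving* if it ever increased — this makes
  the objective trace provably non-increasing, which the tests assert;
* IRLS variance weights are floored at $10^{-9}$ and coefficients with
  $|\beta| < 10^{-10}$ after convergence are snapped to exact zero for
  honest sparsity accounting;
* a location whose positively-weighted outcomes are all 0 or all 1 has
  no interior optimum; such degenerate fits return the null model with
  the intercept at the logit of the pseudo-count-shrunken weighted mean
  $(\sum w_j y_j + 0.5)/(\sum w_j + 1)$ and are flagged, never silently
  dropped — this keeps the CV loops total.

Correctness is established against three independent routes: base R's
`glm.fit` IRLS at $\lambda = 0$ (agreement $10^{-6}$), a brute-force
first-order proximal/subgradient minimizer at $\lambda > 0$ (objective
agreement $10^{-4}$ over 50 random small designs), and glmnet with
matched weight scaling as a third-party cross-check.  KKT stationarity
of returned solutions is verified directly to $10^{-6}$.

## Hyperparameter selection

Stage one evaluates an $S \times T$ grid of $(\theta, \lambda)$
candidates by leave-one-out cross-validation.  For bandwidth $\theta_s$
and location $i$, the local model is fitted with the $i$-th kernel row
*minus its own entry* — so the held-out unit influences neither the
weights nor the likelihood — and unit $i$ is scored on its predicted
probability.  The criterion is the summed held-out binomial deviance
$-2[y_i \log \hat\mu_i + (1-y_i)\log(1-\hat\mu_i)]$ with probabilities
clipped to $[10^{-10}, 1-10^{-10}]$; a 0/1 misclassification criterion
is available but is a step function in $\lambda$ and therefore noisier.
Covariates are standardized once globally before the CV loop, not
re-standardized per left-out unit: the transform is part of the model
definition, and per-fold re-standardization would change the meaning of
a coefficient across folds.

Ties in the criterion are broken deterministically toward the smallest
$\theta$, then the largest $\lambda$ (the more parsimonious model).
Stage two refits all $N$ locations at $(\hat\theta, \hat\lambda)$ with
full kernel rows, returning the $N \times (p+1)$ coefficient matrix.

The default `search = "grid"` is exhaustive and reproducible; the
warm-started path already makes the $T$ lambda values cost roughly one
path fit per $(\theta, i)$.  `search = "golden"` interprets efficient
bandwidth search as golden-section refinement over $[\min\theta,
\max\theta]$ under a unimodality assumption, evaluating the full
$\lambda$ path at each probed $\theta$; it can land between grid
points but inherits unimodality as an assumption, which is why it is
not the default.

## Coverage index

The index generalizes Gordon's odds-ratio construction.  For location
$i$, $raw_i = \sum_{m:\hat\beta_{im}\neq 0} e^{\hat\beta_{im}} x_{im}$
— only covariates *surviving* the lasso contribute; an implementation
must guard against $e^0 = 1$ leaking in for excluded covariates, and
the tests check exactly that.  Because covariates are z-scored, raw
scores can be negative; the index is interpreted as a nonnegative
coverage measure, so scores are min-max normalized to $[0,1]$ by
default (`normalization = "minmax"`) and any negatives clipped at zero
under `normalization = "none"`.  With min-max normalization the maximum
index value equals $k$ exactly — a recognizable fingerprint of this
construction.  The adjustment constant
$k = \bar t \sum_i h_i / \sum_i h_i \widetilde{raw}_i$ then calibrates
the household-weighted mean to the known population average $\bar t$;
conservation holds to $10^{-8}$ and doubling $\bar t$ doubles $k$ and
every index value (both tested).  Whether $k$ should multiply before or
after normalization is not determined by the construction itself; both
readings are available through the `normalization` switch, and the
calibration property holds under either.  Missing household counts fall
back to uniform weights with a message.

Validation uses Spearman's rank correlation with average ranks for
ties; the two-sided p-value comes from complete enumeration of all $n!$
permutations for $n \le 9$ and from the $t$-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ otherwise, cross-checked against
`stats::cor.test`.

## Co-clustering

The fitted coefficient matrix (intercept column included — it carries
the local baseline and is part of the location's profile) is
co-clustered by a latent block model: cell $M_{ij}$ is emitted from a
Gaussian whose mean and variance depend only on the (row cluster,
column cluster) pair.  We fit by classification EM — hard assignments,
k-means initialization of both partitions, block parameter updates and
label updates alternated — chosen over a variational E-step because the
complete-data log-likelihood is then provably non-decreasing per
iteration (asserted from the returned trace) and the fit is exactly
deterministic given the seed.  Block variances are floored at
$10^{-6}$; restarts whose clusters empty are discarded and the best of
`n_restarts = 20` runs by final log-likelihood is returned, with an
error only if every restart collapses.  For a sparse coefficient field
one may prefer clustering the binary selection pattern rather than the
values; `family = "bernoulli"` does exactly that on $M \neq 0$.
Cluster-count defaults of 10 x 10 suit census-scale matrices
(thousands of rows, ~90 columns); desk-scale examples use smaller G.
Label recovery is evaluated by adjusted Rand index, never raw label
equality, since block labels are identified only up to permutation.

## Synthetic data

`simulate_gwl_data()` generates the conditions the estimator targets:
$N$ units on the unit square (lattice by default), $p$ z-scored
equicorrelated Gaussian covariates, and active coefficient surfaces
drawn from a mean-zero Gaussian process with squared-exponential
covariance, simulated exactly by Cholesky factorization.  Default
configuration, fixed once for the whole test suite: $N = 200$,
$p = 10$, 3 active covariates, GP lengthscale 0.35 (smooth regional
variation — roughly a third of the domain, so effects change sign a
few times across the map rather than oscillating), effect scale 2
(strong but realistic log-odds effects for z-scored covariates),
equicorrelation 0.2 (census-style mild collinearity), seed 20160524.
These values were chosen as a plausible areal-data emulation, not tuned
to any test outcome; the CV grid used in the end-to-end checks spans
$\theta \in \{0.1, 0.2, 0.4, 0.8, 1.6\}$ with a 10-point automatic
$\lambda$ path, and this problem size keeps the full two-stage fit
under ten seconds on one CPU while leaving the LOO machinery
non-trivial ($5 \times 200$ path fits).

What the generator deliberately does **not** emulate: the joint
distribution of real census covariates (heavy tails, blocks of near
duplicates), polygon geometry and shared-border adjacency, spatially
structured missingness, and outcome misclassification.  Passing the
recovery tests therefore demonstrates internal correctness of the
estimator under its own assumptions — smooth surfaces, exogenous
covariates, Bernoulli sampling — not field performance on survey data.

## Known limitations

* LOO-CV is $O(S \cdot N)$ path fits; at census scale ($N$ in the
  thousands) expect minutes to hours, and the golden-section search or
  a coarser $\theta$ grid becomes attractive.
* Lasso coefficients are shrunk toward zero by design; the index
  weights $e^{\hat\beta}$ inherit that bias (no debiasing refit is
  provided), and coefficient-wise inference (standard errors) is out
  of scope.
* Degenerate local outcomes are handled by a flagged null fit; with
  very small bandwidths and rare outcomes many locations can
  degenerate, which is a sign the bandwidth grid starts too low.
* The adaptive (k-nearest-neighbour) bandwidths and bisquare/tricube
  kernels common in the GWR literature are not implemented; the
  Gaussian kernel's unbounded support is assumed throughout.
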