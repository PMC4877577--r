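# gwlasso

Geographically weighted logistic lasso regression and area-based health
coverage indices in R.

## The problem

Area-based health indices (Jarman, Townsend, Gordon-style coverage
scores) summarize small-area inequality as a weighted combination of
census covariates, with weights traditionally estimated from one global
logistic regression.  That construction assumes the same covariates
matter everywhere and ignores spatial correlation between neighbouring
areas.  `gwlasso` relaxes both assumptions: it estimates a *spatially
varying* coefficient field with built-in variable selection, so every
location gets its own sparse set of predictors, and turns the result
into a calibrated coverage index.  It is aimed at spatial
epidemiologists and health-policy analysts working with areal data
(municipality-level screening rates and census covariates are the
canonical use case).

## The model

At calibration location *i* with coordinates *s_i*, the binary outcome
*y_j* ∈ {0, 1} follows a local logistic model
logit(μ_j) = β_{i0} + x_jᵀ β_i, fitted from all N units with Gaussian
distance-decay weights

    w_ij = exp( −(d_ij / θ)² / 2 ),

where d_ij is the distance between units and θ the kernel bandwidth.
Each local fit minimizes the weight-normalized penalized negative
log-likelihood

    Σ_j w̃_ij ℓ(y_j, η_j)  +  λ [ α‖β_i‖₁ + (1−α)‖β_i‖₂²/2 ],

with w̃ the kernel weights normalized to sum one, α = 1 the lasso
default, and the intercept unpenalized.  The L1 penalty sets locally
irrelevant coefficients to exactly zero, so selection varies across the
map.  (θ, λ) are chosen jointly by leave-one-out cross-validation: unit
*i* is removed from its own kernel row, the full warm-started λ path is
fitted on the remaining N − 1 units, and the held-out binomial deviance
is summed over locations.  The final model is the N × (p + 1) sparse
coefficient matrix refitted at (θ̂, λ̂) with full weights.

Downstream, the package builds a Gordon-style coverage index from the
odds-ratio weighted covariates surviving the lasso,
raw_i = Σ_{m: β̂_im ≠ 0} exp(β̂_im) x_im, rescaled by the adjustment
constant *k* so the household-weighted mean matches a known population
average; co-clusters the coefficient matrix with a Gaussian latent
block model to find area groups with shared predictor profiles; and
validates indices against external rate series by Spearman correlation
(exact permutation p-values for tiny samples).

## Worked example

All estimation stages run on synthetic data with known smooth, sparse
coefficient surfaces:

```r
library(gwlasso)

sim <- simulate_gwl_data(n = 200, p = 10, n_active = 3,
                         households = TRUE)   # seed = 20160524 default
fit <- gwlasso(y ~ . - id - cx - cy - households, data = sim$data,
               coords = ~ cx + cy, theta = c(0.1, 0.2, 0.4, 0.8, 1.6),
               lambda = "auto", nlambda = 10)
fit
#> Geographically weighted logistic lasso
#>   200 locations, 10 covariates
#>   bandwidth theta = 0.2, shrinkage lambda = 0.0302463, alpha = 1 (LOO-CV)
#>   selected covariates per location: median 6 (range 3-9)
```

LOO-CV picked a local bandwidth (θ̂ = 0.2 on the unit square) over the
near-global candidates — the spatial heterogeneity is detected — and
the lasso keeps a median of 6 of the 10 covariates per location (3 are
truly active; kernel smoothing admits some locally correlated extras).

```r
idx <- coverage_index(fit, target_average = 0.1018,
                      households = sim$data$households)
idx
#> Area-based coverage index
#>   200 locations, adjustment constant k = 0.1836 (minmax normalization)
#>   calibrated to household-weighted mean 0.1018
#>   range 0-0.1836, mean 0.1021, median 0.1038, SD 0.03515

spearman_validate(idx$ind, sim$truth$mu)$rho
#> 0.371
```

The index is calibrated exactly (household-weighted mean 0.1018, the
requested population average; *k* is the scale factor achieving it) and
correlates positively with the true underlying success probability.

```r
lb <- latent_block(coef(fit), G_rows = 4, G_cols = 3, seed = 1)
lb
#> Latent block co-clustering (gaussian emissions)
#>   4 row clusters x 3 column clusters, log-likelihood 569.40
#>   row cluster sizes: 52, 17, 27, 104
summary(lb)   # per-cluster membership and top predictor blocks
```

A command-line surface over the same functions (subcommands `simulate`,
`fit`, `index`, `cocluster`, `validate`) ships in
`inst/cli/gwlasso.R`; see the header of that script for usage.

## Vignette

`vignettes/gwlasso-methods.Rmd` documents the model, the solver, the
hyperparameter search, the index construction, the co-clustering
machinery, what the synthetic generator does and does not emulate, and
the package's numerical choices.
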