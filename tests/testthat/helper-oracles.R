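# Independent oracles used across the suite.  These deliberately share no
# code with the package internals.

# normalized elastic-net logistic objective, numerically stable
oracle_objective <- function(X, y, w, b0, beta, lambda, alpha = 1) {
  wt <- w / sum(w)
  eta <- b0 + drop(as.matrix(X) %*% beta)
  nll <- sum(wt * (pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta))
  nll + lambda * (alpha * sum(abs(beta)) +
                    (1 - alpha) / 2 * sum(beta^2))
}

# brute-force first-order minimizer: (sub)gradient steps with a soft-
# threshold projection of the slopes after each step (intercept free)
oracle_prox_lasso <- function(X, y, w, lambda, alpha = 1,
                              n_iter = 30000) {
  X <- as.matrix(X)
  wt <- w / sum(w)
  b0 <- 0; beta <- rep(0, ncol(X))
  X1 <- cbind(1, X)
  L <- 0.25 * max(eigen(crossprod(X1 * sqrt(wt)), symmetric = TRUE,
                        only.values = TRUE)$values)
  s <- 1 / L
  for (it in seq_len(n_iter)) {
    eta <- b0 + drop(X %*% beta)
    r <- wt * (plogis(eta) - y)
    b0 <- b0 - s * sum(r)
    beta <- beta - s * drop(crossprod(X, r))
    beta <- sign(beta) * pmax(abs(beta) - s * lambda * alpha, 0)
    beta <- beta / (1 + s * lambda * (1 - alpha))
  }
  list(intercept = b0, beta = beta)
}

# unpenalized weighted logistic MLE via base R IRLS
oracle_wlogit_mle <- function(X, y, w) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, as.matrix(X)), y, weights = w,
            family = binomial()))
  fit$coefficients
}

# random non-separable small design for solver stress tests; draws with
# (quasi-)separated outcomes are rejected since the unpenalized MLE is
# unbounded there
random_small_design <- function(n_max = 30, p_max = 5) {
  p <- sample(1:p_max, 1)
  n <- sample(max(12, 4 * p):n_max, 1)
  repeat {
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(0.5 * X[, 1]))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    mle <- suppressWarnings(glm.fit(cbind(1, X), y,
                                    family = binomial()))
    if (mle$converged && max(abs(mle$coefficients)) < 8) break
  }
  list(X = X, y = y, w = runif(n, 0.2, 1), n = n, p = p)
}

# all permutations of a vector, recursive enumeration
enumerate_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i)
    lapply(enumerate_permutations(v[-i]), function(pp) c(v[i], pp))),
    recursive = FALSE)
}

# exhaustive two-sided permutation p-value for Spearman's rho
oracle_spearman_perm <- function(a, b) {
  rho_obs <- cor(a, b, method = "spearman")
  rhos <- vapply(enumerate_permutations(seq_along(a)),
                 function(pp) cor(a[pp], b, method = "spearman"),
                 numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# simple inverse-distance-weighted Moran's I for spatial autocorrelation
moran_i <- function(values, coords, decay = 0.1) {
  D <- as.matrix(dist(coords))
  W <- exp(-D / decay); diag(W) <- 0
  v <- values - mean(values)
  (length(v) / sum(W)) * sum(W * outer(v, v)) / sum(v^2)
}
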