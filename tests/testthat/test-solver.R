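test_that("full shrinkage gives the null model with the weighted-logit intercept", {
  X <- cbind(c(1, -1, 0.5, -0.5), c(0.2, -0.3, 1, -1))
  y <- c(1, 1, 0, 0)
  lmax <- wlogit_lambda_max(X, y)
  fit <- wlogit_lasso(X, y, lambda = lmax)
  expect_identical(unname(fit$beta), c(0, 0))
  expect_equal(fit$intercept, qlogis(0.5), tolerance = 1e-10)  # = 0

  # weighted case: intercept is the logit of the weighted outcome mean
  w <- c(3, 1, 1, 2)
  fitw <- wlogit_lasso(X, y, w, lambda = wlogit_lambda_max(X, y, w) * 1.5)
  expect_identical(unname(fitw$beta), c(0, 0))
  expect_equal(fitw$intercept, qlogis(sum(w * y) / sum(w)),
               tolerance = 1e-10)
})

test_that("lambda_max matches its definition and hand computation", {
  # hand example: |0.5*1*0.5 + 0.5*(-1)*(-0.5)| = 0.5
  X <- cbind(c(1, -1)); y <- c(1, 0)
  expect_equal(wlogit_lambda_max(X, y), 0.5)
  expect_identical(unname(wlogit_lasso(X, y, lambda = 0.5)$beta), 0)
  expect_true(wlogit_lasso(X, y, lambda = 0.49)$beta != 0)

  # covariate orthogonal to (y - pbar) under the weights
  X2 <- cbind(c(1, 1, -1, -1)); y2 <- c(1, 0, 1, 0)
  expect_equal(wlogit_lambda_max(X2, y2), 0)

  # weight-normalization invariance: duplicating with halved weights
  set.seed(2)
  X3 <- matrix(rnorm(12), 6, 2); y3 <- c(1, 0, 1, 1, 0, 0)
  lm1 <- wlogit_lambda_max(X3, y3)
  lm2 <- wlogit_lambda_max(rbind(X3, X3), c(y3, y3),
                           rep(0.5, 12))
  expect_equal(lm1, lm2, tolerance = 1e-12)
  expect_error(wlogit_lambda_max(X3, y3, rep(0, 6)), "weight")
})

test_that("just below lambda_max exactly the maximizing covariate enters", {
  set.seed(4)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- rbinom(20, 1, plogis(X[, 1]))
  wt <- rep(1 / 20, 20)
  scores <- abs(drop(crossprod(X, wt * (y - mean(y)))))
  fit <- wlogit_lasso(X, y, lambda = max(scores) * 0.995)
  expect_equal(sum(fit$beta != 0), 1L)
  expect_true(fit$beta[which.max(scores)] != 0)
})

test_that("unpenalized fits match the IRLS oracle and lasso fits satisfy KKT", {
  set.seed(10)
  for (rep in 1:10) {
    d <- random_small_design()
    fit0 <- wlogit_lasso(d$X, d$y, d$w, lambda = 0)
    expect_equal(unname(c(fit0$intercept, fit0$beta)),
                 unname(oracle_wlogit_mle(d$X, d$y, d$w)),
                 tolerance = 1e-6)
    for (lam in c(0.005, 0.05)) {
      fit <- wlogit_lasso(d$X, d$y, d$w, lambda = lam)
      expect_lt(gwlasso:::.wlogit_kkt(d$X, d$y, d$w, fit$intercept,
                                      fit$beta, lam, 1), 1e-6)
    }
  }
})

test_that("reported objective is consistent and non-increasing along iterations", {
  set.seed(12)
  d <- random_small_design()
  fit <- wlogit_lasso(d$X, d$y, d$w, lambda = 0.02, trace = TRUE)
  expect_equal(fit$objective,
               oracle_objective(d$X, d$y, d$w, fit$intercept, fit$beta,
                                0.02), tolerance = 1e-8)
  expect_true(all(diff(fit$obj_trace) <= 1e-10))
})

test_that("solution is invariant to a positive rescaling of the weights", {
  set.seed(13)
  d <- random_small_design()
  f1 <- wlogit_lasso(d$X, d$y, d$w, lambda = 0.03)
  f2 <- wlogit_lasso(d$X, d$y, d$w * 7.3, lambda = 0.03)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-9)
})

test_that("the warm-started path moves from the empty to the full model", {
  set.seed(14)
  X <- matrix(rnorm(80), 20, 4)
  y <- rbinom(20, 1, plogis(X[, 1] - X[, 2]))
  lmax <- wlogit_lambda_max(X, y)
  path <- wlogit_lasso(X, y, lambda = lmax * c(1, 0.5, 0.1, 0.01, 0),
                       trace = FALSE)
  counts <- as.integer(colSums(path$beta != 0))
  expect_identical(counts[1], 0L)
  expect_identical(counts[5], 4L)
  expect_true(all(diff(counts) >= 0))
})

test_that("elastic-net mixing shrinks without exact zeros at alpha = 0", {
  set.seed(15)
  d <- random_small_design()
  lam <- 0.05
  ridge <- wlogit_lasso(d$X, d$y, d$w, lambda = lam, alpha = 0)
  lasso <- wlogit_lasso(d$X, d$y, d$w, lambda = lam, alpha = 1)
  expect_true(all(ridge$beta != 0))
  expect_lt(gwlasso:::.wlogit_kkt(d$X, d$y, d$w, ridge$intercept,
                                  ridge$beta, lam, 0), 1e-6)
  # objective of each solution is best for its own penalty
  expect_lt(oracle_objective(d$X, d$y, d$w, lasso$intercept, lasso$beta,
                             lam, 1),
            oracle_objective(d$X, d$y, d$w, ridge$intercept, ridge$beta,
                             lam, 1) + 1e-10)
})

test_that("weighted-lasso fits agree with glmnet as an independent solver", {
  set.seed(16)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X[, 1]))
  w <- runif(n, 0.3, 1)
  lam <- 0.04
  fit <- wlogit_lasso(X, y, w, lambda = lam)
  gn <- glmnet::glmnet(X, y, family = "binomial",
                       weights = w / sum(w) * n, lambda = lam,
                       standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(fit$beta), unname(as.vector(gn$beta)),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(gn$a0), tolerance = 1e-4)
})

test_that("degenerate all-equal outcomes yield a flagged shrunken null fit", {
  X <- matrix(rnorm(10), 5, 2)
  w <- rep(1, 5)
  fit <- wlogit_lasso(X, rep(1, 5), w, lambda = 0.1)
  expect_true(fit$degenerate)
  expect_identical(unname(fit$beta), c(0, 0))
  expect_equal(fit$intercept, qlogis(5.5 / 6), tolerance = 1e-12)
})

test_that("probability predictions follow the inverse-logit link", {
  X <- matrix(rnorm(10), 5, 2)
  null_fit <- wlogit_lasso(X, c(1, 0, 1, 0, 1), lambda = 10)
  expect_equal(unname(predict_wlogit(null_fit, c(3, -2))),
               plogis(null_fit$intercept))
  fit <- list(intercept = 0, beta = c(qlogis(0.7), 0))
  expect_equal(predict_wlogit(fit, c(1, 5)), 0.7, tolerance = 1e-4)
  # strictly increasing in a coordinate with positive coefficient
  fit2 <- list(intercept = -0.3, beta = c(0.8, -0.2))
  xs <- seq(-2, 2, length.out = 9)
  ps <- sapply(xs, function(v) predict_wlogit(fit2, c(v, 0.5)))
  expect_true(all(diff(ps) > 0))
  expect_error(predict_wlogit(fit2, c(1, 2, 3)), "length")
})

test_that("malformed solver input is rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(wlogit_lasso(X, c(1, 0, 2, 0, 1), lambda = 0.1), "binary")
  expect_error(wlogit_lasso(X, c(1, 0, NA, 0, 1), lambda = 0.1),
               "missing")
  expect_error(wlogit_lasso(X, c(1, 0, 1, 0, 1), lambda = -1), "lambda")
  expect_error(wlogit_lasso(X, c(1, 0, 1, 0, 1), rep(-1, 5),
                            lambda = 0.1), "nonnegative")
})
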