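sim_small <- simulate_gwl_data(n = 60, p = 3, n_active = 1, seed = 77)

test_that("a singleton hyperparameter grid is returned unchanged", {
  cv <- gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
               theta = 0.4, lambda = 0.05)
  expect_equal(cv$theta_hat, 0.4)
  expect_equal(cv$lambda_hat, 0.05)
  expect_equal(dim(cv$criterion), c(1L, 1L))
  expect_equal(cv$criterion_value, cv$criterion[1, 1])
  expect_true(all(cv$n_evaluated == 60))
})

test_that("duplicated lambda candidates give identical columns and deterministic tie-breaks", {
  cv <- gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
               theta = c(0.3, 0.6), lambda = c(0.08, 0.08, 0.02))
  expect_equal(cv$criterion[, 1], cv$criterion[, 2], ignore_attr = TRUE)
  if (which.min(apply(cv$criterion, 2, min)) <= 2) {
    # tie between the duplicated columns resolves to the larger lambda
    expect_equal(cv$lambda_hat, 0.08)
  }
  expect_error(gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
                      theta = numeric(0), lambda = 0.1), "theta")
  expect_error(gwl_cv(sim_small$X[1:2, ], sim_small$data$y[1:2],
                      sim_small$coords[1:2, ], theta = 1, lambda = 0.1),
               "at least 3")
})

test_that("held-out fits are independent of the held-out unit's outcome", {
  X <- sim_small$X; y <- sim_small$data$y
  i <- 7L
  cv1 <- gwl_cv(X, y, sim_small$coords, theta = 0.4,
                lambda = c(0.1, 0.02), keep_fits = TRUE)
  y2 <- y; y2[i] <- 1 - y2[i]
  cv2 <- gwl_cv(X, y2, sim_small$coords, theta = 0.4,
                lambda = c(0.1, 0.02), keep_fits = TRUE)
  # location i's fitted local coefficients do not involve y_i
  expect_equal(cv1$held_out[[1]]$fits[i, , ],
               cv2$held_out[[1]]$fits[i, , ], tolerance = 1e-10)
  # but its held-out criterion contribution changes
  expect_false(isTRUE(all.equal(cv1$held_out[[1]]$per_location[i, ],
                                cv2$held_out[[1]]$per_location[i, ])))
})

test_that("a perfectly predictive covariate drives the held-out deviance to zero", {
  set.seed(21)
  coords <- cbind(runif(40), runif(40))
  x <- c(rnorm(20, -3), rnorm(20, 3))
  X <- cbind(x1 = (x - mean(x)) / sd(x))
  y <- as.integer(x > 0)
  D <- gw_distances(coords)
  cv <- gwl_cv(X, y, coords, theta = 1e6 * max(D), lambda = 0)
  expect_lt(cv$criterion_value, 1e-3)
})

test_that("in the global limit every local fit equals the global logistic MLE", {
  sim <- simulate_gwl_data(n = 50, p = 3, n_active = 1, seed = 5)
  D <- gw_distances(sim$coords)
  fit <- gwlasso(y ~ x1 + x2 + x3, data = sim$data, coords = ~ cx + cy,
                 theta = 1e6 * max(D), lambda = 0)
  B <- coef(fit)
  expect_lt(max(apply(B, 2, function(cc) diff(range(cc)))), 1e-6)
  oracle <- oracle_wlogit_mle(sim$X, sim$data$y, rep(1, 50))
  expect_equal(unname(B[1, ]), unname(oracle), tolerance = 1e-5)
})

test_that("above every local lambda_max the coefficient field is all-null", {
  sim <- simulate_gwl_data(n = 40, p = 4, n_active = 2, seed = 6)
  D <- gw_distances(sim$coords)
  for (th in c(0.2, 0.6)) {
    W <- gw_kernel(D, th)
    lmax_all <- max(sapply(1:40, function(i)
      wlogit_lambda_max(sim$X, sim$data$y, W[i, ])))
    fit <- gwlasso(y ~ x1 + x2 + x3 + x4, data = sim$data,
                   coords = ~ cx + cy, theta = th, lambda = lmax_all)
    B <- coef(fit)
    expect_true(all(B[, -1] == 0))
    null_int <- sapply(1:40, function(i)
      qlogis(sum(W[i, ] * sim$data$y) / sum(W[i, ])))
    expect_equal(unname(B[, 1]), null_int, tolerance = 1e-6)
  }
})

test_that("permuting unit order permutes the coefficient field identically", {
  set.seed(30)
  perm <- sample(60)
  d <- sim_small$data
  fit <- gwlasso(y ~ x1 + x2 + x3, data = d, coords = ~ cx + cy,
                 theta = 0.4, lambda = 0.03)
  fit_p <- gwlasso(y ~ x1 + x2 + x3, data = d[perm, ],
                   coords = ~ cx + cy, theta = 0.4, lambda = 0.03)
  expect_equal(unname(coef(fit_p)), unname(coef(fit)[perm, ]),
               tolerance = 1e-8)
})

test_that("CV prefers a local bandwidth when coefficients vary in space", {
  sim <- simulate_gwl_data(n = 100, p = 3, n_active = 2,
                           effect_scale = 3, lengthscale = 0.25,
                           seed = 42)
  D <- gw_distances(sim$coords)
  th_big <- 1e6 * max(D)
  cv <- gwl_cv(sim$X, sim$data$y, sim$coords,
               theta = c(0.15, th_big), lambda = "auto", nlambda = 6)
  crit_by_theta <- apply(cv$criterion, 1, min)
  expect_lt(crit_by_theta[1], crit_by_theta[2])
  expect_equal(cv$theta_hat, 0.15)
})

test_that("an S-bandwidth grid costs exactly S x N warm-started path fits", {
  ctr <- gwlasso:::.fit_counter
  ctr$n_path_fits <- 0L
  invisible(gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
                   theta = c(0.3, 0.6), lambda = c(0.1, 0.03, 0.01)))
  # the whole 3-value lambda path is one warm-started fit per (theta, i)
  expect_identical(ctr$n_path_fits, 2L * 60L)
})

test_that("automatic lambda grids are geometric, decreasing and anchored", {
  lam <- gwl_lambda_grid(sim_small$X, sim_small$data$y, nlambda = 8)
  expect_length(lam, 8)
  expect_true(all(diff(lam) < 0))
  expect_equal(lam[8] / lam[1], 1e-3, tolerance = 1e-10)
  expect_equal(lam[1],
               wlogit_lambda_max(sim_small$X, sim_small$data$y))
  expect_true(sd(diff(log(lam))) < 1e-10)  # geometric spacing
})

test_that("golden-section bandwidth search refines toward the grid optimum", {
  cv_grid <- gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
                    theta = c(0.1, 0.3, 0.9), lambda = c(0.08, 0.02))
  cv_gold <- gwl_cv(sim_small$X, sim_small$data$y, sim_small$coords,
                    theta = c(0.1, 0.9), lambda = c(0.08, 0.02),
                    search = "golden")
  expect_gte(cv_gold$theta_hat, 0.1)
  expect_lte(cv_gold$theta_hat, 0.9)
  expect_lte(cv_gold$criterion_value, cv_grid$criterion_value * 1.05)
})

test_that("total sparsity is monotone along the lambda path at fixed theta", {
  sim <- simulate_gwl_data(n = 40, p = 5, n_active = 2, seed = 9)
  D <- gw_distances(sim$coords)
  W <- gw_kernel(D, 0.4)
  lmax_all <- max(sapply(1:40, function(i)
    wlogit_lambda_max(sim$X, sim$data$y, W[i, ])))
  lambdas <- lmax_all * c(1, 0.5, 0.2, 0.05, 0.01)
  counts <- sapply(lambdas, function(lam) {
    B <- gwlasso:::.gwl_fit_field(sim$X, sim$data$y, W, lam, 1, 1e-7)$B
    sum(B[, -1] != 0)
  })
  expect_identical(counts[1], 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("the fitted model exposes the standard S3 surface", {
  d <- sim_small$data
  fit <- gwlasso(y ~ x1 + x2 + x3, data = d, coords = ~ cx + cy,
                 theta = 0.4, lambda = 0.03)
  expect_s3_class(fit, "gwlasso")
  expect_equal(dim(coef(fit)), c(60L, 4L))
  expect_equal(fitted(fit), predict(fit))
  expect_equal(predict(fit, newdata = d), fitted(fit), tolerance = 1e-12)
  expect_equal(plogis(predict(fit, type = "link")), predict(fit))
  r <- residuals(fit)
  expect_equal(sign(r), sign(d$y - fitted(fit)))
  expect_equal(residuals(fit, "response"), d$y - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.gwlasso")
  expect_output(print(fit), "Geographically weighted")
  expect_output(print(s), "Selected covariates")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(60L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  grDevices::pdf(NULL)
  val <- plot(fit)
  grDevices::dev.off()
  expect_length(val, 60)
  expect_error(gwlasso(x1 ~ x2, data = d, coords = ~ cx + cy,
                       theta = 1, lambda = 0), "binary")
})
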