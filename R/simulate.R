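#' Simulate a spatial dataset with smooth, sparse coefficient surfaces
#'
#' Generates areal data matching the modelling assumptions of
#' [gwlasso()]: N units on the unit square, p standardized covariates, and
#' a binary outcome whose log-odds depend on a small number of covariates
#' through spatially smooth, location-varying coefficients.  Active
#' coefficient surfaces are drawn from a mean-zero Gaussian process with a
#' squared-exponential covariance (simulated exactly by Cholesky
#' factorization of the covariance matrix); the remaining p - n_active
#' covariates have coefficient exactly zero everywhere, giving a known
#' ground truth for selection and surface-recovery checks.
#'
#' @param n number of areal units.
#' @param p number of covariates.
#' @param n_active number of covariates with nonzero coefficient surfaces
#'   (the first `n_active` columns).
#' @param lengthscale spatial correlation length of the coefficient
#'   surfaces, in coordinate units on the unit square.  Smaller values
#'   give rougher, more local effects.
#' @param effect_scale marginal standard deviation of the active
#'   coefficient surfaces (coefficients are on the standardized-covariate
#'   scale).
#' @param rho equicorrelation of the covariates, in `[0, 1)`.
#' @param layout `"grid"` for a near-square lattice, `"uniform"` for
#'   uniform random locations.
#' @param intercept constant log-odds offset controlling the expected
#'   prevalence (0 gives prevalence 1/2 on average).
#' @param households if `TRUE`, draw positive household counts per unit
#'   (log-normal), for index-calibration exercises.
#' @param seed integer seed; the output is fully reproducible.
#' @return list with
#'   \describe{
#'     \item{data}{data frame: `id`, coordinates `cx`, `cy`, covariates
#'       `x1..xp`, outcome `y`, and `households` when requested,}
#'     \item{coords}{N x 2 coordinate matrix,}
#'     \item{X}{the N x p standardized covariate matrix,}
#'     \item{truth}{list with `beta_true` (N x (p+1), intercept first),
#'       `active` (indices of active covariates), `eta`, `mu`.}
#'   }
#' @examples
#' sim <- simulate_gwl_data(n = 50, p = 4, n_active = 2, seed = 1)
#' colMeans(sim$truth$beta_true[, -1] != 0)  # active columns only
#' @export
simulate_gwl_data <- function(n = 200, p = 10, n_active = 3,
                              lengthscale = 0.35, effect_scale = 2,
                              rho = 0.2, layout = c("grid", "uniform"),
                              intercept = 0, households = FALSE,
                              seed = 20160524) {
  layout <- match.arg(layout)
  if (n < 2 || p < 1 || n_active < 0 || n_active > p)
    stop("need n >= 2, p >= 1 and 0 <= n_active <= p")
  if (lengthscale <= 0 || effect_scale < 0)
    stop("'lengthscale' must be > 0 and 'effect_scale' >= 0")
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  coords <- if (layout == "grid") {
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
    g <- expand.grid(cx = seq(0, 1, length.out = nx),
                     cy = seq(0, 1, length.out = ny))
    as.matrix(g[seq_len(n), ])
  } else {
    cbind(cx = runif(n), cy = runif(n))
  }
  rownames(coords) <- NULL

  # equicorrelated Gaussian covariates, then z-scored
  z_common <- rnorm(n)
  X <- sqrt(rho) * z_common + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  X <- standardize_covariates(X)$X
  colnames(X) <- paste0("x", seq_len(p))

  beta_true <- matrix(0, n, p + 1L)
  colnames(beta_true) <- c("(Intercept)", colnames(X))
  beta_true[, 1L] <- intercept
  active <- seq_len(n_active)
  if (n_active > 0) {
    D <- as.matrix(dist(coords))
    K <- exp(-0.5 * (D / lengthscale)^2)
    L <- chol(K + diag(1e-8, n))
    for (k in active)
      beta_true[, k + 1L] <- effect_scale * drop(crossprod(L, rnorm(n)))
  }

  eta <- beta_true[, 1L] + rowSums(beta_true[, -1L, drop = FALSE] * X)
  mu <- plogis(eta)
  y <- rbinom(n, 1L, mu)

  data <- data.frame(id = sprintf("u%03d", seq_len(n)), coords, X,
                     y = y, check.names = FALSE)
  if (households)
    data$households <- exp(rnorm(n, mean = log(500), sd = 0.8))
  list(data = data, coords = coords, X = X,
       truth = list(beta_true = beta_true, active = active,
                    eta = eta, mu = mu))
}

#' Simulate a continuous-rate spatial dataset
#'
#' Variant of [simulate_gwl_data()] whose observable is a continuous rate
#' (the true success probability plus Gaussian noise, clipped to
#' `[0, 1]`), for exercising median binarization end-to-end.
#'
#' @inheritParams simulate_gwl_data
#' @param noise_sd standard deviation of the additive observation noise.
#' @param ... passed to [simulate_gwl_data()].
#' @return as [simulate_gwl_data()], with a `rates` column in `data` and
#'   no `y` column (binarize with [binarize_median()]).
#' @export
simulate_gwl_rates <- function(n = 200, p = 10, n_active = 3,
                               noise_sd = 0.05, seed = 20160524, ...) {
  sim <- simulate_gwl_data(n = n, p = p, n_active = n_active, seed = seed,
                           ...)
  rates <- pmin(pmax(sim$truth$mu + rnorm(n, sd = noise_sd), 0), 1)
  sim$data$y <- NULL
  sim$data$rates <- rates
  sim
}
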