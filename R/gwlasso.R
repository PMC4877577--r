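#' Automatic shrinkage-parameter grid
#'
#' Builds a glmnet-style geometric lambda sequence anchored at the largest
#' local \eqn{\lambda_{max}} scale in the data: the anchor is
#' [wlogit_lambda_max()] evaluated at the kernel row with the greatest total
#' mass (the most "global" calibration location), and the grid decreases
#' geometrically to `ratio` times the anchor.
#'
#' @param X covariate matrix (standardized).
#' @param y binary outcome vector.
#' @param W kernel weight matrix, e.g. from [gw_kernel()]; omit for uniform
#'   weights.
#' @param nlambda number of grid points.
#' @param alpha elastic-net mixing parameter.
#' @param ratio smallest-to-largest lambda ratio.
#' @return decreasing numeric vector of length `nlambda`.
#' @export
gwl_lambda_grid <- function(X, y, W = NULL, nlambda = 10, alpha = 1,
                            ratio = 1e-3) {
  w <- if (is.null(W)) rep(1, length(y)) else W[which.max(rowSums(W)), ]
  anchor <- wlogit_lambda_max(X, y, w, alpha)
  if (anchor <= 0) anchor <- 1e-3
  exp(seq(log(anchor), log(anchor * ratio), length.out = nlambda))
}

# One LOO pass at a single bandwidth: for each location i fit the full
# descending-lambda path with weights W[i, -i] and score the held-out unit.
# Returns criterion and prediction per (i, lambda) plus the fitted local
# coefficients when keep_fits = TRUE.
.gwl_loo_theta <- function(X, y, W, lambda, alpha, criterion, tol,
                           keep_fits = FALSE) {
  n <- nrow(X); p <- ncol(X); nl <- length(lambda)
  crit <- matrix(NA_real_, n, nl)
  mu <- matrix(NA_real_, n, nl)
  degenerate <- logical(n)
  fits <- if (keep_fits) array(NA_real_, c(n, p + 1L, nl)) else NULL
  for (i in seq_len(n)) {
    path <- wlogit_lasso(X[-i, , drop = FALSE], y[-i], W[i, -i],
                         lambda = lambda, alpha = alpha, tol = tol)
    degenerate[i] <- isTRUE(path$degenerate)
    eta <- path$intercept + drop(X[i, , drop = FALSE] %*% path$beta)
    mu[i, ] <- plogis(eta)
    crit[i, ] <- if (criterion == "deviance")
      .bernoulli_deviance(y[i], mu[i, ])
    else
      as.numeric((mu[i, ] > 0.5) != y[i])
    if (keep_fits) fits[i, , ] <- rbind(path$intercept, path$beta)
  }
  list(criterion = colSums(crit), mu = mu, per_location = crit,
       degenerate = degenerate, fits = fits)
}

#' Leave-one-out cross-validation over bandwidth and shrinkage
#'
#' First stage of the two-stage estimator: evaluates the held-out
#' prediction criterion on an S x T grid of kernel bandwidths `theta` and
#' shrinkage parameters `lambda`.  For each bandwidth and each location i,
#' the local model is fitted from the other N - 1 observations only (the
#' i-th row of the kernel matrix with its own entry removed) along the full
#' warm-started lambda path, and unit i is scored on its held-out predicted
#' probability.  The summed criterion is minimized with deterministic
#' tie-breaking: smallest bandwidth first, then the largest (sparsest)
#' lambda.
#'
#' @param X covariate matrix (standardized), N x p.
#' @param y binary outcome vector.
#' @param coords two-column coordinate matrix, or a precomputed distance
#'   matrix from [gw_distances()] (detected by being square).
#' @param theta increasing vector of candidate bandwidths (> 0).
#' @param lambda vector of candidate shrinkage values, or `"auto"` to build
#'   a grid with [gwl_lambda_grid()] at the largest candidate bandwidth.
#' @param nlambda grid size when `lambda = "auto"`.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso).
#' @param criterion held-out loss: `"deviance"` (binomial deviance, with
#'   probabilities clipped away from 0/1) or `"misclassification"`.
#' @param search `"grid"` evaluates every candidate bandwidth;
#'   `"golden"` refines theta by golden-section search on the assumption of
#'   a unimodal criterion, evaluating the full lambda path at each probe.
#' @param metric,minkowski_power,form,cutoff kernel options passed to
#'   [gw_distances()] and [gw_kernel()].
#' @param tol solver convergence tolerance.
#' @param keep_fits if `TRUE`, retain all held-out local coefficient paths
#'   (an N x (p+1) x T array per bandwidth) for diagnostics.
#' @return object of class `"gwl_cv"`: a list with the criterion matrix
#'   (`S x T`), `n_evaluated`, per-bandwidth degenerate-fit counts, the
#'   candidate grids, and the selected `theta_hat`, `lambda_hat`,
#'   `criterion_value`.
#' @examples
#' sim <- simulate_gwl_data(n = 40, p = 2, n_active = 1, seed = 7)
#' cv <- gwl_cv(sim$X, sim$data$y, sim$coords,
#'              theta = c(0.2, 1), lambda = c(0.1, 0.01))
#' cv$theta_hat
#' @seealso [gwlasso()] for the full two-stage fit.
#' @export
gwl_cv <- function(X, y, coords, theta, lambda = "auto", nlambda = 10,
                   alpha = 1,
                   criterion = c("deviance", "misclassification"),
                   search = c("grid", "golden"),
                   metric = "euclidean", minkowski_power = 2,
                   form = "gaussian", cutoff = 0, tol = 1e-7,
                   keep_fits = FALSE) {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("LOO cross-validation needs at least 3 locations")
  if (length(theta) < 1L || any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' candidates must be positive and finite")
  theta <- sort(unique(theta))

  D <- if (is.matrix(coords) && nrow(coords) == ncol(coords) &&
           nrow(coords) == n && isTRUE(all.equal(coords, t(coords))))
    coords
  else
    gw_distances(coords, metric = metric, p = minkowski_power)

  if (identical(lambda, "auto")) {
    W_wide <- gw_kernel(D, max(theta), form = form, cutoff = cutoff)
    lambda <- gwl_lambda_grid(X, y, W_wide, nlambda = nlambda,
                              alpha = alpha)
  }
  if (length(lambda) < 1L || any(!is.finite(lambda)) || any(lambda < 0))
    stop("'lambda' candidates must be nonnegative and finite")
  lambda <- sort(lambda, decreasing = TRUE)

  eval_theta <- function(th) {
    W <- gw_kernel(D, th, form = form, cutoff = cutoff)
    .gwl_loo_theta(X, y, W, lambda, alpha, criterion, tol,
                   keep_fits = keep_fits)
  }

  if (search == "grid") {
    rows <- lapply(theta, eval_theta)
    theta_eval <- theta
  } else {
    # golden-section over [min(theta), max(theta)]; probes accumulate
    gr <- (sqrt(5) - 1) / 2
    lo <- min(theta); hi <- max(theta)
    cache <- new.env(parent = emptyenv())
    probe <- function(th) {
      key <- sprintf("%.12g", th)
      if (!exists(key, envir = cache, inherits = FALSE))
        cache[[key]] <- eval_theta(th)
      min(cache[[key]]$criterion)
    }
    a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
    fa <- probe(a); fb <- probe(b)
    it <- 0L
    while (hi - lo > 1e-3 * (max(theta) - min(theta)) && it < 40L) {
      if (fa <= fb) { hi <- b; b <- a; fb <- fa
        a <- hi - gr * (hi - lo); fa <- probe(a)
      } else { lo <- a; a <- b; fa <- fb
        b <- lo + gr * (hi - lo); fb <- probe(b) }
      it <- it + 1L
    }
    theta_eval <- sort(as.numeric(ls(cache)))
    rows <- lapply(theta_eval, function(th) cache[[sprintf("%.12g", th)]])
  }

  crit <- do.call(rbind, lapply(rows, `[[`, "criterion"))
  dimnames(crit) <- list(theta = sprintf("%.6g", theta_eval),
                         lambda = sprintf("%.6g", lambda))
  n_degenerate <- vapply(rows, function(r) sum(r$degenerate), integer(1))
  n_evaluated <- matrix(n, nrow(crit), ncol(crit))

  # argmin with deterministic tie-breaking: theta ascending (rows), lambda
  # descending (columns), so the first minimum row-wise then column-wise.
  best <- which(crit == min(crit), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]

  structure(list(criterion = crit, n_evaluated = n_evaluated,
                 criterion_name = criterion,
                 theta = theta_eval, lambda = lambda, alpha = alpha,
                 n_degenerate = n_degenerate,
                 theta_hat = theta_eval[best[1L]],
                 lambda_hat = lambda[best[2L]],
                 criterion_value = min(crit),
                 held_out = if (keep_fits) rows else NULL),
            class = "gwl_cv")
}

#' @export
print.gwl_cv <- function(x, ...) {
  cat("Leave-one-out CV for geographically weighted logistic lasso\n")
  cat(sprintf("  criterion: summed held-out %s over %d x %d (theta x lambda) grid\n",
              x$criterion_name, length(x$theta), length(x$lambda)))
  cat(sprintf("  selected:  theta = %g, lambda = %g (criterion %.4f)\n",
              x$theta_hat, x$lambda_hat, x$criterion_value))
  if (any(x$n_degenerate > 0))
    cat(sprintf("  degenerate local fits at %d bandwidth(s)\n",
                sum(x$n_degenerate > 0)))
  invisible(x)
}

# Final per-location fits (second stage): full kernel weights, fixed
# (theta, lambda).  Returns the N x (p+1) coefficient matrix plus flags.
.gwl_fit_field <- function(X, y, W, lambda, alpha, tol) {
  n <- nrow(X); p <- ncol(X)
  B <- matrix(0, n, p + 1L)
  converged <- logical(n); degenerate <- logical(n)
  for (i in seq_len(n)) {
    fit <- wlogit_lasso(X, y, W[i, ], lambda = lambda, alpha = alpha,
                        tol = tol)
    B[i, ] <- c(fit$intercept, fit$beta)
    converged[i] <- isTRUE(fit$converged)
    degenerate[i] <- isTRUE(fit$degenerate)
  }
  colnames(B) <- c("(Intercept)", colnames(X))
  list(B = B, converged = converged, degenerate = degenerate)
}

#' Geographically weighted logistic lasso regression
#'
#' Fits a spatially varying coefficient model for a binary areal outcome:
#' at every calibration location i a logistic regression is estimated from
#' all N units, weighted by a Gaussian distance-decay kernel centred on i,
#' with an elastic-net penalty that sets locally irrelevant coefficients to
#' exactly zero.  When `theta` or `lambda` is not supplied, both are
#' selected jointly by leave-one-out cross-validation ([gwl_cv()]): the
#' first stage scores every candidate pair on held-out units, the second
#' stage refits all N local models at the selected pair.  The result is an
#' N x (p+1) sparse coefficient matrix (one row per location, intercept
#' first).
#'
#' Covariates are standardized (mean 0, sample sd 1) by default and
#' coefficients are reported on the standardized scale; the transform is
#' stored in the fitted object for prediction and index construction.
#'
#' @param formula model formula; the response must be binary 0/1 (use
#'   [binarize_median()] to dichotomize a continuous rate first).
#' @param data data frame holding the response, covariates and coordinate
#'   columns.
#' @param coords one-sided formula naming the coordinate columns
#'   (e.g. `~ x + y`) or a two-column matrix of coordinates.
#' @param theta kernel bandwidth; a single value fixes it, a vector gives
#'   CV candidates (default: 8 values spanning the distance distribution).
#' @param lambda shrinkage; a single value fixes it, a vector gives CV
#'   candidates, `"auto"` (default) builds a geometric grid.
#' @param nlambda size of the automatic lambda grid.
#' @param alpha elastic-net mixing in `[0, 1]`; 1 (default) is the lasso.
#' @param criterion,search,metric,minkowski_power,form,cutoff,tol passed to
#'   [gwl_cv()] / [gw_kernel()].
#' @param standardize standardize covariates before fitting (recommended;
#'   the penalty treats all slopes symmetrically).
#' @return object of class `"gwlasso"` with components `coefficients`
#'   (N x (p+1) matrix), `theta`, `lambda`, `alpha`, `cv` (the `"gwl_cv"`
#'   object, or `NULL` when both hyperparameters were fixed),
#'   `fitted.values`, `y`, `X` (standardized design), `center`, `scale`,
#'   `coords`, `converged`, `degenerate`, and the usual `call`/`terms`.
#'   Methods: [coef()], [predict.gwlasso()], [fitted()], [residuals()],
#'   [summary.gwlasso()], [plot.gwlasso()], [simulate()].
#' @examples
#' sim <- simulate_gwl_data(n = 60, p = 3, n_active = 1, seed = 11)
#' d <- sim$data
#' fit <- gwlasso(y ~ x1 + x2 + x3, data = d, coords = ~ cx + cy,
#'                theta = 0.5, lambda = 0.02)
#' head(coef(fit))
#' @references Brunsdon C, Fotheringham AS, Charlton M (1996).
#'   Geographically weighted regression: a method for exploring spatial
#'   nonstationarity. Geographical Analysis 28(4), 281-298.
#'
#'   Friedman J, Hastie T, Tibshirani R (2010). Regularization paths for
#'   generalized linear models via coordinate descent. Journal of
#'   Statistical Software 33(1).
#' @export
gwlasso <- function(formula, data, coords, theta = NULL, lambda = "auto",
                    nlambda = 10, alpha = 1,
                    criterion = c("deviance", "misclassification"),
                    search = c("grid", "golden"),
                    metric = "euclidean", minkowski_power = 2,
                    form = "gaussian", cutoff = 0, tol = 1e-7,
                    standardize = TRUE) {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  cl <- match.call()

  mf <- model.frame(formula, data, na.action = stats::na.fail)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1)))
    stop("response must be binary 0/1; binarize a continuous rate first ",
         "(see binarize_median())")
  y <- as.numeric(y)
  mt <- attr(mf, "terms")
  X_raw <- model.matrix(mt, mf)
  icpt <- match("(Intercept)", colnames(X_raw))
  if (!is.na(icpt)) X_raw <- X_raw[, -icpt, drop = FALSE]
  if (ncol(X_raw) < 1L) stop("at least one covariate is required")

  if (inherits(coords, "formula")) {
    cv_names <- all.vars(coords)
    if (length(cv_names) != 2L)
      stop("'coords' formula must name exactly two columns")
    coords <- as.matrix(data[, cv_names, drop = FALSE])
  } else coords <- as.matrix(coords)
  if (nrow(coords) != length(y))
    stop("'coords' and model data must have the same number of rows")

  if (standardize) {
    Xs <- standardize_covariates(X_raw)
    X <- Xs$X; center <- Xs$center; scale <- Xs$scale
  } else {
    X <- X_raw
    center <- setNames(rep(0, ncol(X)), colnames(X))
    scale <- setNames(rep(1, ncol(X)), colnames(X))
  }

  D <- gw_distances(coords, metric = metric, p = minkowski_power)

  fixed_theta <- is.numeric(theta) && length(theta) == 1L
  fixed_lambda <- is.numeric(lambda) && length(lambda) == 1L
  cv <- NULL
  if (fixed_theta && fixed_lambda) {
    theta_hat <- theta; lambda_hat <- lambda
  } else {
    theta_cand <- if (is.null(theta)) {
      dq <- stats::quantile(D[upper.tri(D)], c(0.05, 1))
      exp(seq(log(max(dq[1L], 1e-6)), log(dq[2L]), length.out = 8))
    } else theta
    cv <- gwl_cv(X, y, D, theta = theta_cand, lambda = lambda,
                 nlambda = nlambda, alpha = alpha, criterion = criterion,
                 search = search, form = form, cutoff = cutoff, tol = tol)
    theta_hat <- cv$theta_hat; lambda_hat <- cv$lambda_hat
  }

  W <- gw_kernel(D, theta_hat, form = form, cutoff = cutoff)
  field <- .gwl_fit_field(X, y, W, lambda_hat, alpha, tol)
  eta <- field$B[, 1L] + rowSums(field$B[, -1L, drop = FALSE] * X)
  structure(list(call = cl, terms = mt,
                 coefficients = field$B,
                 theta = theta_hat, lambda = lambda_hat, alpha = alpha,
                 cv = cv, criterion = criterion,
                 fitted.values = plogis(eta), linear.predictors = eta,
                 y = y, X = X, center = center, scale = scale,
                 coords = coords, metric = metric, form = form,
                 converged = field$converged,
                 degenerate = field$degenerate,
                 standardized = standardize),
            class = "gwlasso")
}
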