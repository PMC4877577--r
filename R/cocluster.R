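#' Co-cluster a coefficient matrix with a latent block model
#'
#' Simultaneously partitions the rows (areal units) and columns
#' (coefficients) of a matrix into G_rows x G_cols homogeneous blocks,
#' revealing groups of areas that share a predictor profile.  The model is
#' a latent block mixture: every cell M_ij is emitted from a distribution
#' whose parameters depend only on the (row cluster, column cluster) pair.
#' Gaussian emissions (block mean and variance) suit a real-valued sparse
#' coefficient field; `family = "bernoulli"` instead models the binary
#' nonzero pattern `M != 0` (block-wise selection probabilities).
#'
#' Fitting is by classification EM: starting from k-means partitions of
#' the rows and columns, block parameters and hard cluster assignments are
#' alternately updated, which makes the complete-data log-likelihood
#' non-decreasing at every iteration.  The best of `n_restarts` runs (by
#' final log-likelihood) is returned; runs that collapse an empty cluster
#' are discarded, and an error is raised only if every restart collapses.
#'
#' @param M numeric matrix to co-cluster, e.g. `coef(fit)` from
#'   [gwlasso()].
#' @param G_rows,G_cols number of row and column clusters (must not exceed
#'   the matrix dimensions).
#' @param n_restarts independent restarts (default 20).
#' @param seed integer seed making the fit reproducible.
#' @param family `"gaussian"` (values) or `"bernoulli"` (nonzero pattern).
#' @param max_iter,tol convergence controls: stop when the relative
#'   log-likelihood change falls below `tol` or after `max_iter`
#'   iterations.
#' @param var_floor lower bound on block variances, preventing singular
#'   blocks.
#' @return object of class `"latent_block"`: `row_labels` (in 1..G_rows),
#'   `col_labels`, `block_means`, `block_variances` (Gaussian family),
#'   `log_likelihood`, `logLik_trace` of the returned run,
#'   `n_restarts_used`, `seed`, `n_iter`, `family`.
#' @examples
#' set.seed(1)
#' M <- matrix(rnorm(40 * 6), 40, 6)
#' M[1:20, 1:3] <- M[1:20, 1:3] + 4
#' lb <- latent_block(M, G_rows = 2, G_cols = 2, seed = 3, n_restarts = 5)
#' table(lb$row_labels[1:20])
#' @references Govaert G, Nadif M (2003). Clustering with block mixture
#'   models. Pattern Recognition 36(2), 463-473.
#' @export
latent_block <- function(M, G_rows = 10, G_cols = 10, n_restarts = 20,
                         seed = 1, family = c("gaussian", "bernoulli"),
                         max_iter = 500, tol = 1e-8, var_floor = 1e-6) {
  family <- match.arg(family)
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("'M' must be finite")
  n <- nrow(M); q <- ncol(M)
  if (G_rows > n || G_cols > q)
    stop("cluster counts cannot exceed the matrix dimensions")
  if (G_rows < 1 || G_cols < 1) stop("cluster counts must be >= 1")
  if (family == "bernoulli") M <- (M != 0) * 1

  set.seed(as.integer(seed) %% .Machine$integer.max)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)

  best <- NULL
  n_used <- 0L
  for (r in seq_len(n_restarts)) {
    n_used <- n_used + 1L
    run <- .lbm_cem_run(M, G_rows, G_cols, restart_seeds[r], family,
                        max_iter, tol, var_floor)
    if (is.null(run)) next  # empty-cluster collapse
    if (is.null(best) || run$log_likelihood > best$log_likelihood)
      best <- run
  }
  if (is.null(best))
    stop("all restarts collapsed an empty cluster; reduce G")
  best$n_restarts_used <- n_used
  best$seed <- seed
  best$family <- family
  best$dimnames <- dimnames(M)
  class(best) <- "latent_block"
  best
}

# initial partition: k-means, falling back to quantile slicing on means
# when k-means cannot produce the requested number of clusters
.lbm_init <- function(V, G) {
  if (G == 1L) return(rep(1L, nrow(V)))
  km <- tryCatch(kmeans(V, centers = G, nstart = 3, iter.max = 50),
                 error = function(e) NULL)
  if (!is.null(km) && length(unique(km$cluster)) == G)
    return(km$cluster)
  cut(rank(rowMeans(V), ties.method = "first"), G, labels = FALSE)
}

.lbm_cem_run <- function(M, G, H, run_seed, family, max_iter, tol,
                         var_floor) {
  set.seed(run_seed)
  n <- nrow(M); q <- ncol(M)
  z <- .lbm_init(M, G)        # row labels
  w <- .lbm_init(t(M), H)     # column labels
  M2 <- M * M

  indmat <- function(lab, K) {
    out <- matrix(0, length(lab), K)
    out[cbind(seq_along(lab), lab)] <- 1
    out
  }

  params <- function(z, w) {
    Zr <- indmat(z, G); Zc <- indmat(w, H)
    ng <- colSums(Zr); nh <- colSums(Zc)
    if (any(ng == 0) || any(nh == 0)) return(NULL)
    cnt <- outer(ng, nh)
    S1 <- crossprod(Zr, M %*% Zc)
    mu <- S1 / cnt
    if (family == "gaussian") {
      S2 <- crossprod(Zr, M2 %*% Zc)
      sg2 <- pmax(S2 / cnt - mu^2, var_floor)
    } else {
      mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
      sg2 <- mu * (1 - mu)
    }
    list(pi = ng / n, rho = nh / q, mu = mu, sg2 = sg2, Zc = Zc, Zr = Zr,
         nh = nh, ng = ng)
  }

  # log-density sums of all rows (or columns) against every cluster
  score_rows <- function(pr) {
    S1 <- M %*% pr$Zc; S2 <- M2 %*% pr$Zc   # n x H sufficient stats
    sc <- matrix(rep(log(pr$pi), each = n), n, G)
    for (g in seq_len(G)) {
      if (family == "gaussian") {
        a <- -0.5 * log(2 * pi * pr$sg2[g, ])
        sc[, g] <- sc[, g] +
          drop(S2 %*% (-0.5 / pr$sg2[g, ])) +
          drop(S1 %*% (pr$mu[g, ] / pr$sg2[g, ])) +
          sum(pr$nh * (a - 0.5 * pr$mu[g, ]^2 / pr$sg2[g, ]))
      } else {
        sc[, g] <- sc[, g] +
          drop(S1 %*% log(pr$mu[g, ] / (1 - pr$mu[g, ]))) +
          sum(pr$nh * log(1 - pr$mu[g, ]))
      }
    }
    sc
  }

  loglik <- function(pr, z, w) {
    ll <- sum(log(pr$pi)[z]) + sum(log(pr$rho)[w])
    if (family == "gaussian") {
      S2 <- crossprod(pr$Zr, M2 %*% pr$Zc)
      S1 <- crossprod(pr$Zr, M %*% pr$Zc)
      cnt <- outer(pr$ng, pr$nh)
      ll + sum(-0.5 * cnt * log(2 * pi * pr$sg2) -
                 (S2 - 2 * pr$mu * S1 + cnt * pr$mu^2) / (2 * pr$sg2))
    } else {
      S1 <- crossprod(pr$Zr, M %*% pr$Zc)
      cnt <- outer(pr$ng, pr$nh)
      ll + sum(S1 * log(pr$mu) + (cnt - S1) * log(1 - pr$mu))
    }
  }

  trace <- numeric(0)
  ll_old <- -Inf
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    pr <- params(z, w)
    if (is.null(pr)) return(NULL)
    z_new <- max.col(score_rows(pr), ties.method = "first")
    if (length(unique(z_new)) < G) return(NULL)
    z <- z_new
    pr <- params(z, w)

    # column update: same machinery on the transpose
    prT <- list(pi = pr$rho, rho = pr$pi, mu = t(pr$mu), sg2 = t(pr$sg2),
                Zc = pr$Zr, nh = pr$ng)
    sc_cols <- {
      Mt <- t(M); Mt2 <- t(M2)
      S1 <- Mt %*% prT$Zc; S2 <- Mt2 %*% prT$Zc
      sc <- matrix(rep(log(prT$pi), each = q), q, H)
      for (h in seq_len(H)) {
        if (family == "gaussian") {
          a <- -0.5 * log(2 * pi * prT$sg2[h, ])
          sc[, h] <- sc[, h] +
            drop(S2 %*% (-0.5 / prT$sg2[h, ])) +
            drop(S1 %*% (prT$mu[h, ] / prT$sg2[h, ])) +
            sum(prT$nh * (a - 0.5 * prT$mu[h, ]^2 / prT$sg2[h, ]))
        } else {
          sc[, h] <- sc[, h] +
            drop(S1 %*% log(prT$mu[h, ] / (1 - prT$mu[h, ]))) +
            sum(prT$nh * log(1 - prT$mu[h, ]))
        }
      }
      sc
    }
    w_new <- max.col(sc_cols, ties.method = "first")
    if (length(unique(w_new)) < H) return(NULL)
    w <- w_new

    pr <- params(z, w)
    if (is.null(pr)) return(NULL)
    ll <- loglik(pr, z, w)
    trace <- c(trace, ll)
    if (n_iter >= max_iter ||
        (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)))
      break
    ll_old <- ll
  }

  pr <- params(z, w)
  list(row_labels = z, col_labels = w,
       block_means = pr$mu,
       block_variances = if (family == "gaussian") pr$sg2 else
         pr$mu * (1 - pr$mu),
       log_likelihood = trace[length(trace)],
       logLik_trace = trace, n_iter = n_iter)
}

#' @export
print.latent_block <- function(x, ...) {
  cat("Latent block co-clustering (", x$family, " emissions)\n", sep = "")
  cat(sprintf("  %d row clusters x %d column clusters, log-likelihood %.2f\n",
              nrow(x$block_means), ncol(x$block_means),
              x$log_likelihood))
  cat(sprintf("  converged in %d iterations (%d restart(s) used, seed %d)\n",
              x$n_iter, x$n_restarts_used, x$seed))
  cat("  row cluster sizes: ",
      paste(tabulate(x$row_labels, nrow(x$block_means)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tabular report of a latent block co-clustering
#'
#' Summarizes each row cluster (its member units, the column clusters with
#' the largest absolute block means and the covariates they contain) and
#' lists every block's mean, variance and occupancy.
#'
#' @param result a [latent_block()] fit.
#' @param covariate_names optional labels for the matrix columns.
#' @param unit_ids optional labels for the matrix rows.
#' @param top number of top column clusters to report per row cluster.
#' @return object of class `"block_summary"`: list with `blocks` (a data
#'   frame with one row per block: row_cluster, col_cluster, mean,
#'   variance, n_rows, n_cols, occupancy) and `row_clusters` (a list per
#'   row cluster: `units`, `top_col_clusters`, `top_covariates`).
#' @export
block_summary <- function(result, covariate_names = NULL, unit_ids = NULL,
                          top = 3L) {
  stopifnot(inherits(result, "latent_block"))
  z <- result$row_labels; w <- result$col_labels
  G <- nrow(result$block_means); H <- ncol(result$block_means)
  if (is.null(unit_ids)) unit_ids <- as.character(seq_along(z))
  if (is.null(covariate_names))
    covariate_names <- as.character(seq_along(w))
  if (length(unit_ids) != length(z) ||
      length(covariate_names) != length(w))
    stop("label lengths must match the clustered matrix dimensions")

  ng <- tabulate(z, G); nh <- tabulate(w, H)
  blocks <- data.frame(row_cluster = rep(seq_len(G), times = H),
                       col_cluster = rep(seq_len(H), each = G),
                       mean = as.vector(result$block_means),
                       variance = as.vector(result$block_variances),
                       n_rows = rep(ng, times = H),
                       n_cols = rep(nh, each = G))
  blocks$occupancy <- blocks$n_rows * blocks$n_cols

  row_clusters <- lapply(seq_len(G), function(g) {
    ord <- order(abs(result$block_means[g, ]), decreasing = TRUE)
    tc <- utils::head(ord, top)
    list(units = unit_ids[z == g],
         top_col_clusters = tc,
         top_covariates = lapply(tc, function(h) covariate_names[w == h]))
  })
  structure(list(blocks = blocks, row_clusters = row_clusters),
            class = "block_summary")
}

#' @export
summary.latent_block <- function(object, ...) block_summary(object, ...)

#' @export
print.block_summary <- function(x, ...) {
  cat("Block summary (", nrow(x$blocks), " blocks)\n", sep = "")
  ord <- order(abs(x$blocks$mean), decreasing = TRUE)
  cat("Top blocks by |mean|:\n")
  print(utils::head(x$blocks[ord, ], 5L), row.names = FALSE)
  invisible(x)
}
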