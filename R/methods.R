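#' @export
print.gwlasso <- function(x, ...) {
  cat("Geographically weighted logistic lasso\n\n")
  cat("Call:\n  ", deparse(x$call), "\n\n", sep = "")
  nz <- rowSums(x$coefficients[, -1L, drop = FALSE] != 0)
  cat(sprintf("  %d locations, %d covariates\n", nrow(x$coefficients),
              ncol(x$coefficients) - 1L))
  cat(sprintf("  bandwidth theta = %g, shrinkage lambda = %g, alpha = %g%s\n",
              x$theta, x$lambda, x$alpha,
              if (is.null(x$cv)) " (fixed)" else " (LOO-CV)"))
  cat(sprintf("  selected covariates per location: median %g (range %d-%d)\n",
              median(nz), min(nz), max(nz)))
  invisible(x)
}

#' @export
coef.gwlasso <- function(object, ...) object$coefficients

#' @export
fitted.gwlasso <- function(object, ...) object$fitted.values

#' Predictions from a geographically weighted logistic lasso fit
#'
#' Evaluates each location's local model at that location's covariates.
#' With `newdata`, rows must correspond to the N calibration locations (the
#' model's coefficients are defined per location); covariates are
#' standardized with the transform stored in the fit.
#'
#' @param object a fitted [gwlasso()] model.
#' @param newdata optional data frame with the model covariates, one row
#'   per calibration location.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... unused.
#' @return numeric vector of length N.
#' @export
predict.gwlasso <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    X <- model.matrix(tt, model.frame(tt, newdata,
                                      na.action = stats::na.fail))
    icpt <- match("(Intercept)", colnames(X))
    if (!is.na(icpt)) X <- X[, -icpt, drop = FALSE]
    if (nrow(X) != nrow(object$coefficients))
      stop("'newdata' must have one row per calibration location (",
           nrow(object$coefficients), ")")
    X <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
    B <- object$coefficients
    eta <- B[, 1L] + rowSums(B[, -1L, drop = FALSE] * X)
  }
  if (type == "link") eta else plogis(eta)
}

#' @export
residuals.gwlasso <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y; mu <- .clip01(object$fitted.values)
  switch(type,
         response = y - mu,
         pearson  = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) * sqrt(.bernoulli_deviance(y, mu)))
}

#' Summary of a geographically weighted logistic lasso fit
#'
#' @param object a fitted [gwlasso()] model.
#' @param ... unused.
#' @return a `"summary.gwlasso"` list: hyperparameters, per-location
#'   sparsity distribution, per-covariate selection frequencies and mean
#'   absolute coefficients, in-sample deviance, and convergence counts.
#' @export
summary.gwlasso <- function(object, ...) {
  B <- object$coefficients
  slopes <- B[, -1L, drop = FALSE]
  nz_row <- rowSums(slopes != 0)
  sel <- colSums(slopes != 0)
  mean_abs <- colMeans(abs(slopes))
  dev <- sum(.bernoulli_deviance(object$y, object$fitted.values))
  out <- list(call = object$call, theta = object$theta,
              lambda = object$lambda, alpha = object$alpha,
              n = nrow(B), p = ncol(slopes),
              nonzero_per_location = summary(nz_row),
              selection_frequency = sort(sel, decreasing = TRUE),
              mean_abs_coef = sort(mean_abs, decreasing = TRUE),
              deviance = dev,
              n_not_converged = sum(!object$converged),
              n_degenerate = sum(object$degenerate),
              cv = object$cv)
  class(out) <- "summary.gwlasso"
  out
}

#' @export
print.summary.gwlasso <- function(x, ...) {
  cat("Geographically weighted logistic lasso\n\n")
  cat("Call:\n  ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("N = %d locations, p = %d covariates\n", x$n, x$p))
  cat(sprintf("theta = %g, lambda = %g, alpha = %g\n",
              x$theta, x$lambda, x$alpha))
  if (!is.null(x$cv))
    cat(sprintf("LOO-CV criterion (%s) at optimum: %.4f\n",
                x$cv$criterion_name, x$cv$criterion_value))
  cat("\nSelected covariates per location:\n")
  print(x$nonzero_per_location)
  cat("\nMost frequently selected covariates:\n")
  print(utils::head(x$selection_frequency, 5L))
  cat("\nLargest mean |coefficient|:\n")
  print(round(utils::head(x$mean_abs_coef, 5L), 4L))
  cat(sprintf("\nIn-sample deviance: %.2f\n", x$deviance))
  if (x$n_not_converged > 0 || x$n_degenerate > 0)
    cat(sprintf("Flags: %d non-converged, %d degenerate local fits\n",
                x$n_not_converged, x$n_degenerate))
  invisible(x)
}

#' Map a fitted coefficient surface or sparsity pattern
#'
#' Base-graphics map of the calibration locations, coloured by the number
#' of selected covariates, a chosen coefficient surface, or the fitted
#' probabilities.
#'
#' @param x a fitted [gwlasso()] model.
#' @param what `"nonzero"`, `"coef"` or `"fitted"`.
#' @param covariate covariate name (or column index into the coefficient
#'   matrix) when `what = "coef"`.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the plotted values.
#' @export
plot.gwlasso <- function(x, what = c("nonzero", "coef", "fitted"),
                         covariate = NULL, ...) {
  what <- match.arg(what)
  val <- switch(what,
    nonzero = rowSums(x$coefficients[, -1L, drop = FALSE] != 0),
    fitted = x$fitted.values,
    coef = {
      if (is.null(covariate))
        stop("specify 'covariate' for what = \"coef\"")
      x$coefficients[, covariate]
    })
  pal <- grDevices::hcl.colors(64, "viridis")
  idx <- cut(val, breaks = 64, labels = FALSE, include.lowest = TRUE)
  if (all(is.na(idx))) idx <- rep(32L, length(val))  # constant surface
  graphics::plot(x$coords, col = pal[idx], pch = 19,
                 xlab = "x", ylab = "y",
                 main = switch(what,
                               nonzero = "Selected covariates per location",
                               fitted = "Fitted probability",
                               coef = paste("Coefficient surface:",
                                            covariate)), ...)
  invisible(val)
}

#' @export
simulate.gwlasso <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- matrix(rbinom(length(mu) * nsim, 1L, mu), ncol = nsim)
  colnames(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}
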