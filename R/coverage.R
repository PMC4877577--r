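#' Median (or custom-threshold) binarization of a continuous rate
#'
#' Dichotomizes a rate series for use as the binary outcome of
#' [gwlasso()]: `y_i = 1` iff the rate strictly exceeds the threshold
#' (sample median by default), so ties at the threshold map to 0 and at
#' most half the units are coded 1.
#'
#' @param rates finite numeric vector, length >= 2.
#' @param threshold cut point; defaults to `median(rates)`.
#' @return integer 0/1 vector with attribute `threshold`.
#' @examples
#' binarize_median(c(1, 2, 3, 4))  # 0 0 1 1
#' @export
binarize_median <- function(rates, threshold = median(rates)) {
  if (length(rates) < 2L || any(!is.finite(rates)))
    stop("'rates' must be finite and of length >= 2")
  if (max(rates) == min(rates))
    stop("all rates are identical; there is no variation to model")
  y <- as.integer(rates > threshold)
  attr(y, "threshold") <- threshold
  y
}

#' Standardize covariates to z-scores
#'
#' Centres each column at its mean and scales by the sample (n - 1)
#' standard deviation, recording the transform so raw values can be
#' recovered.
#'
#' @param X numeric matrix or data frame of covariates.
#' @return list with `X` (standardized matrix), `center`, `scale`.
#' @export
standardize_covariates <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  if (any(scale == 0)) {
    bad <- colnames(X)[scale == 0]
    if (is.null(bad)) bad <- which(scale == 0)
    stop("constant covariate(s) cannot be standardized: ",
         paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  list(X = Xs, center = center, scale = scale)
}

#' Area-based health coverage index from a fitted coefficient field
#'
#' Gordon-style index construction: each location's raw score is the sum,
#' over the covariates surviving the lasso at that location, of the
#' estimated odds ratio times the (standardized) covariate value,
#' \deqn{raw_i = \sum_{m:\ \hat\beta_{im} \neq 0}
#'       \exp(\hat\beta_{im})\, x_{im}.}
#' Covariates with a zero coefficient contribute exactly nothing.  Raw
#' scores are optionally min-max normalized to `[0, 1]`, negatives are
#' clipped to 0, and the adjustment constant
#' \eqn{k = \bar t \sum_i h_i / \sum_i h_i\,\widetilde{raw}_i}
#' rescales the scores so that their household-weighted mean equals the
#' known population average outcome \eqn{\bar t} (e.g. a national
#' screening rate).
#'
#' @param object a fitted [gwlasso()] model, or an N x (p+1) coefficient
#'   matrix with the intercept in column 1.
#' @param target_average known population average to calibrate to (> 0),
#'   on the proportion scale (e.g. 0.1018 for 10.18%).
#' @param households optional positive household counts per location;
#'   uniform weights are used (with a message) when absent.
#' @param X covariate matrix (standardized, without intercept column);
#'   taken from the fitted model when `object` is a `"gwlasso"`.
#' @param normalization `"minmax"` (default) rescales raw scores to
#'   `[0, 1]` before calibration; `"none"` only clips negatives to 0.
#' @return object of class `"coverage_index"`: list with `ind` (the
#'   calibrated index, >= 0), `raw` (unscaled scores), `k`,
#'   `target_average`, `households`, `normalization`.
#' @examples
#' B <- cbind(0, matrix(c(log(2), log(2)), 2, 1))  # one surviving covariate
#' idx <- coverage_index(B, target_average = 0.15, X = cbind(c(0.5, 1)),
#'                       normalization = "none")
#' idx$ind
#' @export
coverage_index <- function(object, target_average, households = NULL,
                           X = NULL,
                           normalization = c("minmax", "none")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(target_average) || length(target_average) != 1L ||
      !is.finite(target_average) || target_average <= 0)
    stop("'target_average' must be a single positive number")
  if (inherits(object, "gwlasso")) {
    B <- object$coefficients
    if (is.null(X)) X <- object$X
  } else B <- as.matrix(object)
  if (is.null(X)) stop("'X' is required when 'object' is a plain matrix")
  X <- as.matrix(X)
  slopes <- B[, -1L, drop = FALSE]
  if (!all(dim(slopes) == dim(X)))
    stop("coefficient matrix and covariates are not conformable")
  n <- nrow(X)
  if (is.null(households)) {
    message("no household counts supplied; using uniform weights")
    households <- rep(1, n)
  }
  if (length(households) != n || any(!is.finite(households)) ||
      any(households <= 0))
    stop("'households' must be positive counts, one per location")

  # odds-ratio weights on surviving covariates only: exp(0) must not leak in
  contrib <- exp(slopes) * X
  contrib[slopes == 0] <- 0
  raw <- rowSums(contrib)

  scaled <- if (normalization == "minmax") {
    rng <- range(raw)
    if (rng[1L] == rng[2L])
      stop("raw scores are constant; min-max normalization is undefined")
    (raw - rng[1L]) / (rng[2L] - rng[1L])
  } else raw
  scaled <- pmax(scaled, 0)

  denom <- sum(households * scaled)
  if (denom <= 0)
    stop("all scores are zero; cannot calibrate the adjustment constant")
  k <- target_average * sum(households) / denom
  structure(list(ind = k * scaled, raw = raw, k = k,
                 target_average = target_average, households = households,
                 normalization = normalization),
            class = "coverage_index")
}

#' @export
print.coverage_index <- function(x, ...) {
  cat("Area-based coverage index\n")
  cat(sprintf("  %d locations, adjustment constant k = %.4g (%s normalization)\n",
              length(x$ind), x$k, x$normalization))
  cat(sprintf("  calibrated to household-weighted mean %.4g\n",
              x$target_average))
  cat(sprintf("  range %.4g-%.4g, mean %.4g, median %.4g, SD %.4g\n",
              min(x$ind), max(x$ind), mean(x$ind), median(x$ind),
              sd(x$ind)))
  invisible(x)
}

#' @export
summary.coverage_index <- function(object, ...) {
  c(summary(object$ind), k = object$k,
    target_average = object$target_average)
}

#' Spearman rank correlation with permutation or t-approximate p-value
#'
#' Validates an index against an external rate series by Spearman's rank
#' correlation.  Ties receive average ranks.  For N <= 9 the two-sided
#' p-value is exact, from complete enumeration of all N! permutations; for
#' larger N the usual t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom is
#' used.
#'
#' @param ind numeric vector (e.g. a coverage index).
#' @param external paired numeric vector of the same length (>= 4).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_validate(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_validate <- function(ind, external) {
  if (inherits(ind, "coverage_index")) ind <- ind$ind
  ind <- as.numeric(ind); external <- as.numeric(external)
  n <- length(ind)
  if (length(external) != n) stop("'ind' and 'external' must be paired")
  if (n < 4L) stop("need at least 4 paired observations")
  if (any(!is.finite(ind)) || any(!is.finite(external)))
    stop("inputs must be finite")
  if (sd(ind) == 0 || sd(external) == 0)
    stop("zero variance: the correlation is undefined")

  r1 <- rank(ind); r2 <- rank(external)
  rho <- cor(r1, r2)

  if (n <= 9L) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(pp) cor(r1[pp], r2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1:n as an n! x n matrix (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
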