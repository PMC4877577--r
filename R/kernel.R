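#' Pairwise distances between areal-unit coordinates
#'
#' Computes the dense N x N matrix of distances between unit coordinates,
#' used to calibrate the spatial weighting kernel.  Planar metrics are
#' delegated to [stats::dist()]; great-circle distances use the haversine
#' formula and expect longitude/latitude in degrees.
#'
#' @param coords two-column numeric matrix or data frame of coordinates
#'   (x, y; for `metric = "haversine"`, longitude and latitude in degrees).
#'   Row names, if present, are carried over to the result.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"minkowski"`,
#'   `"haversine"`.
#' @param p power of the Minkowski distance (`p = 2` is Euclidean,
#'   `p = 1` Manhattan); must be >= 1.
#' @return N x N symmetric numeric matrix with zero diagonal and attributes
#'   `metric` (and `minkowski_power` where relevant).  Haversine distances
#'   are in kilometres; planar distances are in coordinate units.
#' @examples
#' xy <- cbind(x = c(0, 3, 1), y = c(0, 4, 1))
#' gw_distances(xy)[1, 2]               # 5: the 3-4-5 triangle
#' gw_distances(xy, "manhattan")[1, 2]  # 7
#' @seealso [gw_kernel()]
#' @export
gw_distances <- function(coords,
                         metric = c("euclidean", "manhattan", "minkowski",
                                    "haversine"),
                         p = 2) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("'coords' must have exactly two columns (x, y)")
  storage.mode(coords) <- "double"
  bad <- which(!is.finite(coords[, 1L]) | !is.finite(coords[, 2L]))
  if (length(bad))
    stop("non-finite coordinates in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (nrow(coords) < 2L) stop("need at least two locations")

  if (metric == "haversine") {
    lon <- coords[, 1L]; lat <- coords[, 2L]
    if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
      stop("haversine metric requires lon in [-180, 180], lat in [-90, 90]")
    D <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
    dimnames(D) <- NULL
  } else {
    if (metric == "minkowski" && (!is.finite(p) || p < 1))
      stop("'p' (minkowski power) must be >= 1")
    D <- as.matrix(dist(coords, method = metric, p = p))
    dimnames(D) <- NULL
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2  # enforce exact symmetry against rounding
  rownames(D) <- colnames(D) <- rownames(coords)
  attr(D, "metric") <- metric
  if (metric == "minkowski") attr(D, "minkowski_power") <- p
  D
}

#' Gaussian distance-decay kernel weights
#'
#' Converts a distance matrix into spatial observation weights
#' `w_ij = exp(-(d_ij / theta)^2 / 2)` (the Brunsdon-style Gaussian kernel;
#' set `form = "gaussian-squared"` for `exp(-(d_ij / theta)^2)`, which is the
#' same family with the bandwidth rescaled by sqrt(2)).  The kernel has
#' unbounded support, so all weights are strictly positive; `w_ii = 1`.
#'
#' @param D symmetric nonnegative distance matrix, e.g. from
#'   [gw_distances()].
#' @param theta bandwidth, in the units of `D`; must be > 0.  Larger values
#'   approach a global (unweighted) model.
#' @param form kernel convention, `"gaussian"` (the 1/2-exponent form,
#'   default) or `"gaussian-squared"`.
#' @param cutoff weights below this value are truncated to exactly zero
#'   (default 0, i.e. no truncation).
#' @return N x N matrix of weights in `[0, 1]` with unit diagonal and
#'   attribute `theta`.
#' @examples
#' D <- gw_distances(cbind(c(0, 1), c(0, 0)))
#' gw_kernel(D, theta = 1)[1, 2]  # exp(-0.5)
#' @export
gw_kernel <- function(D, theta, form = c("gaussian", "gaussian-squared"),
                      cutoff = 0) {
  form <- match.arg(form)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("'theta' must be a single positive number")
  D <- as.matrix(D)
  z <- (D / theta)^2
  W <- if (form == "gaussian") exp(-0.5 * z) else exp(-z)
  diag(W) <- 1
  if (cutoff > 0) W[W < cutoff] <- 0
  attr(W, "theta") <- theta
  attr(W, "form") <- form
  W
}
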