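#' Read a spatial dataset from delimited text
#'
#' Reads a CSV of areal units and maps its columns onto the roles the
#' model needs: unit id, coordinates, a binary outcome or a continuous
#' rate (binarized by the sample median unless a threshold is given),
#' optional household counts, and covariates.  Rows with missing values in
#' any used column are rejected with a row-numbered error; covariates are
#' standardized and the transform recorded.
#'
#' @param path CSV file with a header row.
#' @param id,x,y column names of the unit label and coordinates.
#' @param outcome column name of a binary 0/1 outcome (exclusive with
#'   `rate`).
#' @param rate column name of a continuous rate to binarize.
#' @param threshold binarization threshold (default: sample median).
#' @param households optional column of positive household counts.
#' @param covariates character vector of covariate columns; default every
#'   remaining numeric column.
#' @param standardize z-score the covariates (default `TRUE`).
#' @return object of class `"gwl_data"`: list with `ids`, `coords`, `X`
#'   (standardized), `X_raw`, `y`, `rates`, `households`, `center`,
#'   `scale`, `covariate_names`.
#' @export
read_gwl_data <- function(path, id = "id", x = "x", y = "y",
                          outcome = NULL, rate = NULL, threshold = NULL,
                          households = NULL, covariates = NULL,
                          standardize = TRUE) {
  df <- read.csv(path, check.names = FALSE)
  need <- c(id, x, y, outcome, rate, households)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(outcome) && !is.null(rate))
    stop("supply either 'outcome' or 'rate', not both")
  if (is.null(covariates))
    covariates <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          need)
  if (!length(covariates)) stop("no covariate columns found")
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  roles <- c(need, covariates)
  if (anyDuplicated(roles))
    stop("column roles must be disjoint: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))

  used <- df[, roles, drop = FALSE]
  bad <- which(!complete.cases(used))
  if (length(bad))
    stop("missing values in used columns at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (anyDuplicated(df[[id]])) stop("duplicated unit ids in column '", id,
                                    "'")

  X_raw <- as.matrix(used[, covariates, drop = FALSE])
  if (!is.numeric(X_raw))
    stop("non-numeric covariate values in: ",
         paste(covariates[!vapply(used[covariates], is.numeric,
                                  logical(1))], collapse = ", "))
  coords_mat <- as.matrix(used[, c(x, y)])
  rates_vec <- if (!is.null(rate)) used[[rate]] else NULL
  y <- if (!is.null(outcome)) {
    v <- used[[outcome]]
    if (!all(v %in% c(0, 1))) stop("'", outcome, "' must be binary 0/1")
    as.integer(v)
  } else if (!is.null(rate)) {
    if (is.null(threshold)) binarize_median(rates_vec)
    else binarize_median(rates_vec, threshold = threshold)
  } else NULL

  hh <- if (!is.null(households)) {
    v <- used[[households]]
    if (any(v <= 0)) stop("household counts must be positive")
    v
  } else NULL

  if (standardize) {
    st <- standardize_covariates(X_raw)
  } else {
    st <- list(X = X_raw,
               center = setNames(rep(0, ncol(X_raw)), covariates),
               scale = setNames(rep(1, ncol(X_raw)), covariates))
  }
  structure(list(ids = as.character(used[[id]]),
                 coords = coords_mat,
                 X = st$X, X_raw = X_raw, y = y, rates = rates_vec,
                 households = hh, center = st$center, scale = st$scale,
                 covariate_names = covariates),
            class = "gwl_data")
}

#' @export
print.gwl_data <- function(x, ...) {
  cat(sprintf("Spatial dataset: %d units, %d covariates%s%s\n",
              length(x$ids), ncol(x$X),
              if (!is.null(x$y)) ", binary outcome" else "",
              if (!is.null(x$households)) ", household counts" else ""))
  invisible(x)
}

# atomic write: build in a temp file in the same directory, then rename
.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write to ", path)
  invisible(path)
}

#' Write and re-read model artifacts as CSV / JSON / GeoJSON
#'
#' Writers use full-precision float formatting so that re-reading
#' reproduces the numbers exactly; all files are written atomically
#' (temp-file rename).
#'
#' @param fit a fitted [gwlasso()] model (or coefficient matrix for
#'   `write_gwl_coef`).
#' @param path output file path.
#' @param ids optional unit identifiers.
#' @return the path, invisibly (`read_gwl_coef` returns a list with `ids`
#'   and the coefficient matrix `B`).
#' @name gwl_io
NULL

#' @rdname gwl_io
#' @export
write_gwl_coef <- function(fit, path, ids = NULL) {
  B <- if (inherits(fit, "gwlasso")) coef(fit) else as.matrix(fit)
  if (is.null(ids)) ids <- rownames(B)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(B)))
  df <- data.frame(unit_id = ids, B, check.names = FALSE)
  .write_atomic(function(tmp)
    write.csv(format(df, digits = 17, trim = TRUE), tmp,
              row.names = FALSE, quote = FALSE), path)
}

#' @rdname gwl_io
#' @export
read_gwl_coef <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  B <- as.matrix(df[, -1L, drop = FALSE])
  rownames(B) <- df[[1L]]
  list(ids = as.character(df[[1L]]), B = B)
}

#' @rdname gwl_io
#' @param cv a `"gwl_cv"` object.
#' @export
write_gwl_cv <- function(cv, path) {
  stopifnot(inherits(cv, "gwl_cv"))
  grid <- expand.grid(lambda = cv$lambda, theta = cv$theta)[, 2:1]
  df <- data.frame(theta = grid$theta, lambda = grid$lambda,
                   criterion = as.vector(t(cv$criterion)),
                   n_evaluated = as.vector(t(cv$n_evaluated)))
  .write_atomic(function(tmp)
    write.csv(format(df, digits = 17, trim = TRUE), tmp,
              row.names = FALSE, quote = FALSE), path)
}

#' @rdname gwl_io
#' @param index a [coverage_index()] result.
#' @export
write_gwl_index <- function(index, path, ids = NULL) {
  stopifnot(inherits(index, "coverage_index"))
  if (is.null(ids)) ids <- as.character(seq_along(index$ind))
  df <- data.frame(unit_id = ids, raw = index$raw, ind = index$ind)
  .write_atomic(function(tmp)
    write.csv(format(df, digits = 17, trim = TRUE), tmp,
              row.names = FALSE, quote = FALSE), path)
}

#' @rdname gwl_io
#' @param coords N x 2 coordinate matrix (x, y order; lon/lat for
#'   GeoJSON).
#' @export
write_gwl_geojson <- function(index, coords, path, ids = NULL) {
  stopifnot(inherits(index, "coverage_index"))
  coords <- as.matrix(coords)
  if (nrow(coords) != length(index$ind))
    stop("'coords' must have one row per index value")
  if (is.null(ids)) ids <- as.character(seq_along(index$ind))
  features <- lapply(seq_along(index$ind), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(coords[i, 1L], coords[i, 2L])),
    properties = list(unit_id = ids[i], ind = index$ind[i],
                      raw = index$raw[i])))
  fc <- list(type = "FeatureCollection", features = features)
  .write_atomic(function(tmp)
    jsonlite::write_json(fc, tmp, auto_unbox = TRUE, digits = NA), path)
}

#' @rdname gwl_io
#' @param config named list echoed verbatim into the metadata.
#' @export
write_gwl_metadata <- function(fit, path, config = list()) {
  meta <- list(package = "gwlasso",
               version = as.character(packageVersion("gwlasso")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config)
  if (inherits(fit, "gwlasso"))
    meta <- c(meta, list(theta = fit$theta, lambda = fit$lambda,
                         alpha = fit$alpha, n = nrow(coef(fit)),
                         p = ncol(coef(fit)) - 1L))
  .write_atomic(function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), path)
}
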