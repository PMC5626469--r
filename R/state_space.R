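#' Build a discrete state space for activity centers
#'
#' Constructs a regular pixel grid covering the bounding box of a set of
#' locations plus a buffer, and attaches a per-pixel density covariate.
#' Activity centers are represented by pixel index and evaluated at pixel
#' centroids.  All coordinates are kilometres in a planar (projected)
#' system.
#'
#' The grid tiles the buffered bounding box with square pixels of side
#' `resolution`; when the box width is not a multiple of the resolution the
#' overhang is split evenly between the two sides, so edge-pixel centroids
#' can fall outside the box by less than half a pixel.
#'
#' @param points two-column matrix or data frame of (x, y) locations (km)
#'   whose extent the state space must cover (typically all traps and
#'   auxiliary fixes).
#' @param buffer nonnegative buffer (km) added on every side.
#' @param resolution pixel side length (km); the study default is 4 km.
#' @param covariate per-pixel density covariate: either a function of
#'   `(x, y)` vectors returning one value per pixel, or a numeric vector
#'   with one value per pixel (row-major is irrelevant — values are matched
#'   to centroid order: x fastest, then y).  Defaults to 0 everywhere
#'   (homogeneous density).
#' @return An object of class `scr_state_space`: a list with elements
#'   `centroids` (n_pixels x 2 matrix), `resolution`, `covariate`,
#'   `n_pixels`, and grid metadata (`nx`, `ny`, `x0`, `y0`).
#' @examples
#' sp <- scr_state_space(cbind(c(0, 10), c(0, 10)), buffer = 21, resolution = 4)
#' sp$n_pixels  # 169 pixels (13 x 13)
#' @export
scr_state_space <- function(points, buffer, resolution, covariate = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("no locations supplied to build the state space")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (km)")
  if (buffer < 0) stop("buffer must be nonnegative")
  if (any(!is.finite(points))) stop("non-finite coordinates in 'points'")

  axis_grid <- function(lo, hi) {
    w <- (hi - lo) + 2 * buffer
    n <- max(1L, as.integer(ceiling(w / resolution - 1e-9)))
    overhang <- n * resolution - w
    start <- (lo - buffer) - overhang / 2
    list(n = n, centers = start + resolution * (seq_len(n) - 0.5))
  }
  gx <- axis_grid(min(points[, 1]), max(points[, 1]))
  gy <- axis_grid(min(points[, 2]), max(points[, 2]))
  centroids <- cbind(
    x = rep(gx$centers, times = gy$n),
    y = rep(gy$centers, each = gx$n)
  )
  n_pixels <- nrow(centroids)

  cov_vals <- if (is.null(covariate)) {
    rep(0, n_pixels)
  } else if (is.function(covariate)) {
    as.numeric(covariate(centroids[, 1], centroids[, 2]))
  } else {
    as.numeric(covariate)
  }
  if (length(cov_vals) != n_pixels)
    stop(sprintf("covariate has %d values but the grid has %d pixels",
                 length(cov_vals), n_pixels))
  if (any(!is.finite(cov_vals))) stop("covariate values must be finite")

  structure(
    list(centroids = centroids, resolution = resolution,
         covariate = cov_vals, n_pixels = n_pixels,
         nx = gx$n, ny = gy$n,
         x0 = gx$centers[1] - resolution / 2,
         y0 = gy$centers[1] - resolution / 2),
    class = "scr_state_space"
  )
}

#' @export
print.scr_state_space <- function(x, ...) {
  cat(sprintf("SCR state space: %d pixels (%d x %d) at %g km resolution\n",
              x$n_pixels, x$nx, x$ny, x$resolution))
  cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f] km\n",
              x$x0, x$x0 + x$nx * x$resolution,
              x$y0, x$y0 + x$ny * x$resolution))
  cat(sprintf("  covariate range: [%.3f, %.3f]\n",
              min(x$covariate), max(x$covariate)))
  invisible(x)
}

#' Pixel probabilities of the inhomogeneous density model
#'
#' Per-pixel probability that an activity center falls in each pixel under
#' the log-linear intensity model \eqn{\log \mu(s_g) = \beta_1 c_g} with
#' per-pixel covariate \eqn{c_g}, normalised over the state space:
#' \eqn{\pi_g = \mu(s_g) / \sum_h \mu(s_h)}.  The intensity intercept
#' cancels under normalisation and is therefore fixed at zero and never
#' estimated.
#'
#' @param space an [scr_state_space] object.
#' @param beta1 slope of log intensity on the pixel covariate.
#' @return numeric vector of probabilities summing to 1.
#' @export
pixel_probabilities <- function(space, beta1) {
  stopifnot(inherits(space, "scr_state_space"))
  if (!is.finite(beta1)) stop("beta1 must be finite")
  eta <- beta1 * space$covariate
  eta <- eta - max(eta)          # overflow guard
  w <- exp(eta)
  w / sum(w)
}

#' Standardize the time-since-last-check covariate
#'
#' Centers and scales a trap-by-occasion covariate using only the cells
#' where the trap was operational (sample standard deviation, n - 1
#' denominator).  Non-operational cells are set to 0; they never enter the
#' likelihood.
#'
#' @param time_raw J x K numeric matrix of raw values (days).
#' @param operation J x K binary matrix; 1 where the trap was operational.
#' @return J x K matrix of standardized values; active cells have mean 0
#'   and unit sample variance.  If all active values are identical the
#'   covariate is uninformative: a zero matrix is returned with a warning.
#' @export
standardize_time_covariate <- function(time_raw, operation) {
  time_raw <- as.matrix(time_raw)
  operation <- as.matrix(operation)
  if (!all(dim(time_raw) == dim(operation)))
    stop("time_raw and operation must have the same dimensions")
  if (!all(operation %in% c(0, 1))) stop("operation entries must be 0 or 1")
  out <- matrix(0, nrow(time_raw), ncol(time_raw))
  act <- operation == 1
  vals <- time_raw[act]
  if (length(vals) == 0L) return(out)
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    warning("time covariate is constant over operational cells; returning zeros")
    return(out)
  }
  out[act] <- (vals - mean(vals)) / s
  out
}

#' Define a trap array
#'
#' Bundles trap coordinates, trap type, the operation matrix and the
#' (standardized) time-since-last-check covariate.
#'
#' @param coords J x 2 matrix of trap coordinates (km).
#' @param type character vector of length J with values `"hair"` or
#'   `"rub"` (hair trap vs rub tree); internally coded 0/1 with hair traps
#'   as the reference category.
#' @param operation J x K binary matrix (1 = trap operational in occasion).
#' @param time_raw J x K matrix of days since last check; standardized
#'   internally via [standardize_time_covariate()].  May be omitted, in
#'   which case the covariate is 0 everywhere.
#' @param ids optional trap identifiers (default `T1..TJ`).
#' @return An object of class `scr_traps`.
#' @export
scr_traps <- function(coords, type, operation, time_raw = NULL, ids = NULL) {
  coords <- as.matrix(coords)
  J <- nrow(coords)
  type <- as.character(type)
  if (length(type) != J) stop("'type' must have one entry per trap")
  bad <- setdiff(unique(type), c("hair", "rub"))
  if (length(bad))
    stop(sprintf("unknown trap type '%s' (expected 'hair' or 'rub')", bad[1]))
  operation <- as.matrix(operation)
  if (nrow(operation) != J) stop("operation matrix must have one row per trap")
  if (!all(operation %in% c(0, 1))) stop("operation entries must be 0 or 1")
  K <- ncol(operation)
  if (is.null(time_raw)) {
    time_std <- matrix(0, J, K)
    time_raw <- matrix(0, J, K)
  } else {
    time_raw <- as.matrix(time_raw)
    if (!all(dim(time_raw) == c(J, K)))
      stop("time_raw must match the operation matrix dimensions")
    if (any(time_raw[operation == 1] < 0))
      stop("time_raw must be nonnegative")
    time_std <- standardize_time_covariate(time_raw, operation)
  }
  if (is.null(ids)) ids <- paste0("T", seq_len(J))
  dimnames(coords) <- dimnames(operation) <- NULL
  dimnames(time_raw) <- dimnames(time_std) <- NULL
  storage.mode(operation) <- "integer"
  structure(
    list(ids = as.character(ids), coords = coords,
         type = ifelse(type == "rub", 1L, 0L), type_label = type,
         operation = operation, time_raw = time_raw, time_std = time_std,
         J = J, K = K),
    class = "scr_traps"
  )
}

#' @export
print.scr_traps <- function(x, ...) {
  cat(sprintf("SCR trap array: %d traps (%d hair, %d rub) x %d occasions; %d active trap-occasions\n",
              x$J, sum(x$type == 0L), sum(x$type == 1L), x$K, sum(x$operation)))
  invisible(x)
}

# squared Euclidean distances between traps (J) and pixel centroids (G)
trap_pixel_dist2 <- function(traps, space) {
  dx <- outer(traps$coords[, 1], space$centroids[, 1], "-")
  dy <- outer(traps$coords[, 2], space$centroids[, 2], "-")
  dx * dx + dy * dy
}

# index of the pixel whose centroid is nearest to (x, y)
nearest_pixel <- function(space, x, y) {
  d2 <- (space$centroids[, 1] - x)^2 + (space$centroids[, 2] - y)^2
  which.min(d2)
}
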