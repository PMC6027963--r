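# Distance-decay spatial weights: the probabilistic range machinery.

#' Logistic distance-decay spatial weight
#'
#' Weight of one site's presence/absence status in another site's occurrence
#' probability, as a logistic function of their geographic distance:
#' \deqn{W = \frac{1}{1 + e^{k(\ln(d + \delta) - \ln(d_0))}}
#'         = \frac{1}{1 + ((d + \delta)/d_0)^k}}
#' where `d0` is the half-weight distance (the separation at which W = 0.5)
#' and `k` controls the steepness of the decay. A small constant offset
#' `offset` (default 0.1 km) is added to every distance so that the logarithm
#' is defined at d = 0; the logarithm is natural.
#'
#' @param d numeric vector of distances, km (>= 0).
#' @param k dimensionless steepness, > 0.
#' @param d0 half-weight distance, km, > 0.
#' @param offset additive distance offset, km, >= 0 (default 0.1).
#' @return numeric vector of weights in (0, 1), monotone decreasing in `d`.
#' @examples
#' spatial_weight(c(10, 30, 50, 75), k = 5, d0 = 30)
#' @export
spatial_weight <- function(d, k, d0, offset = 0.1) {
  check_smoothing(k, d0, offset)
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
    stop("'d' must be finite numeric distances (km)")
  if (any(d < 0)) stop("'d' must be non-negative")
  1 / (1 + exp(k * (log(d + offset) - log(d0))))
}

check_smoothing <- function(k, d0, offset) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(d0), length(d0) == 1L, is.finite(d0), d0 > 0,
            is.numeric(offset), length(offset) == 1L, is.finite(offset),
            offset >= 0)
  invisible(TRUE)
}

#' Pairwise inter-site distance matrix
#'
#' Builds the symmetric site-by-site distance matrix (km) from a site table.
#' Geographic mode uses great-circle (haversine) distances on WGS84 decimal
#' degrees with mean Earth radius 6371.0088 km; planar mode treats `x`/`y`
#' columns as km and uses Euclidean distance; precomputed mode validates and
#' returns a user-supplied square matrix.
#'
#' @param sites data frame with columns `site_id` and either `lon`/`lat`
#'   (haversine) or `x`/`y` (euclidean). Ignored in precomputed mode except
#'   for optional label checking.
#' @param mode one of `"haversine"`, `"euclidean"`, `"precomputed"`.
#' @param dist_matrix square numeric matrix of km distances, required when
#'   `mode = "precomputed"`; must be symmetric with zero diagonal.
#' @return square numeric matrix of km distances, dimnames = site ids.
#' @export
pairwise_distance <- function(sites, mode = c("haversine", "euclidean", "precomputed"),
                              dist_matrix = NULL) {
  mode <- match.arg(mode)
  if (mode == "precomputed") {
    if (is.null(dist_matrix)) stop("precomputed mode requires 'dist_matrix'")
    d <- as.matrix(dist_matrix)
    if (nrow(d) != ncol(d)) stop("precomputed distance matrix must be square")
    if (anyNA(d) || any(!is.finite(d))) stop("distance matrix has non-finite entries")
    if (any(d < 0)) stop("distances must be non-negative")
    if (max(abs(d - t(d))) > 1e-8) stop("precomputed distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-8)) stop("precomputed distance matrix must have zero diagonal")
    d <- (d + t(d)) / 2
    diag(d) <- 0
    if (!is.null(sites) && !is.null(rownames(d)) &&
        !identical(rownames(d), as.character(sites$site_id)))
      stop("distance matrix labels do not match site table")
    return(d)
  }

  sites <- validate_sites(sites, mode)
  n <- nrow(sites)
  if (n < 2L) stop("need at least 2 sites")
  ids <- as.character(sites$site_id)

  if (mode == "haversine") {
    p <- cbind(sites$lon, sites$lat)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      # mean Earth radius 6371.0088 km
      d[i, j] <- geosphere::distHaversine(p[i, ], p[j, , drop = FALSE],
                                          r = 6371008.8) / 1000
    }
    d <- d + t(d)
  } else {
    d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  }
  dimnames(d) <- list(ids, ids)
  d
}

validate_sites <- function(sites, mode = "haversine") {
  stopifnot(is.data.frame(sites))
  if (!"site_id" %in% names(sites)) stop("site table needs a 'site_id' column")
  ids <- as.character(sites$site_id)
  if (anyDuplicated(ids)) stop("site ids must be unique")
  if (mode == "haversine") {
    if (!all(c("lon", "lat") %in% names(sites)))
      stop("geographic mode needs 'lon' and 'lat' columns")
    if (anyNA(sites$lon) || anyNA(sites$lat)) stop("missing coordinates")
    if (any(sites$lat < -90 | sites$lat > 90)) stop("latitude outside [-90, 90]")
    if (any(sites$lon < -180 | sites$lon > 180)) stop("longitude outside [-180, 180]")
  } else if (mode == "euclidean") {
    if (!all(c("x", "y") %in% names(sites)))
      stop("planar mode needs 'x' and 'y' columns (km)")
    if (anyNA(sites$x) || anyNA(sites$y)) stop("missing coordinates")
  }
  sites
}

#' Spatial weight matrix
#'
#' Applies [spatial_weight()] elementwise to a distance matrix and sets the
#' diagonal to exactly 1 (a site always contributes fully to its own
#' occurrence probability, overriding the value the offset formula would
#' give at d = 0).
#'
#' @param dist square symmetric km distance matrix (e.g. from
#'   [pairwise_distance()]).
#' @inheritParams spatial_weight
#' @return symmetric matrix with entries in (0, 1] and unit diagonal.
#' @export
weight_matrix <- function(dist, k, d0, offset = 0.1) {
  check_smoothing(k, d0, offset)
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (anyNA(d) || any(!is.finite(d)) || any(d < 0))
    stop("distance matrix must be finite and non-negative")
  W <- spatial_weight(d, k, d0, offset)
  dim(W) <- dim(d)
  diag(W) <- 1
  dimnames(W) <- dimnames(d)
  W
}
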