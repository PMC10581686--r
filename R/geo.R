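# Geographic statistics on occurrence points (lon/lat, WGS84-style degrees).

.earth_radius_km <- 6371

.check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("invalid coordinates: non-finite values")
  if (any(lat < -90 | lat > 90)) stop("invalid coordinates: |lat| > 90")
  if (any(lon < -180 | lon > 360)) stop("invalid coordinates: lon out of range")
  invisible(TRUE)
}

#' Great-circle distance between points (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised).
#' @return Distance in kilometres on a sphere of radius 6371 km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  torad <- pi / 180
  dlat <- (lat2 - lat1) * torad
  dlon <- (lon2 - lon1) * torad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * torad) * cos(lat2 * torad) * sin(dlon / 2)^2
  2 * .earth_radius_km * asin(pmin(1, sqrt(a)))
}

#' Occurrence dispersion: mean pairwise great-circle distance
#'
#' Range-size proxy robust to uneven sampling effort: the average distance
#' between all unordered pairs of a species' occurrence points. A single
#' point yields 0. Exact duplicate points are kept by default (they carry
#' information about recording density); set `dedupe = TRUE` to drop them.
#' For very large point sets the pairwise mean is estimated from a seeded
#' random subsample of pairs.
#'
#' @param points A data.frame/matrix with columns `lon`, `lat`, or a
#'   two-column matrix (lon, lat).
#' @param method `"haversine"` (km, default) or `"euclidean"` (degrees;
#'   for cross-checks only).
#' @param dedupe Drop exact duplicate points first? Default `FALSE`.
#' @param max_exact_points Above this many points (default 5000), estimate
#'   from `n_pairs` random pairs instead of full enumeration.
#' @param n_pairs Number of subsampled pairs in the large-n regime (1e6).
#' @param seed Seed for the pair subsample (only used in the large-n regime).
#' @return Mean pairwise distance (km for haversine).
#' @export
#' @examples
#' dispersion_range(data.frame(lon = c(0, 1, 2), lat = c(0, 0, 0)))
dispersion_range <- function(points, method = c("haversine", "euclidean"),
                             dedupe = FALSE, max_exact_points = 5000,
                             n_pairs = 1e6, seed = 1L) {
  method <- match.arg(method)
  pts <- .as_points(points)
  .check_coords(pts$lon, pts$lat)
  if (dedupe) pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(0)
  dist_fun <- function(i, j) {
    if (method == "haversine")
      haversine_km(pts$lon[i], pts$lat[i], pts$lon[j], pts$lat[j])
    else
      sqrt((pts$lon[i] - pts$lon[j])^2 + (pts$lat[i] - pts$lat[j])^2)
  }
  if (n <= max_exact_points) {
    idx <- utils::combn(n, 2L)
    mean(dist_fun(idx[1L, ], idx[2L, ]))
  } else {
    set.seed(seed)
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over off-diagonal pairs
    mean(dist_fun(i, j))
  }
}

.as_points <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("lon", "lat") %in% names(points))) {
    if (ncol(points) >= 2L) names(points)[1:2] <- c("lon", "lat")
    else stop("points must have lon and lat columns")
  }
  if (nrow(points) < 1L) stop("at least one occurrence point required")
  points[, c("lon", "lat")]
}

#' Spherical centroid of occurrence points
#'
#' Mean of the unit position vectors, converted back to lon/lat. Unlike a
#' naive coordinate average this is safe across the antimeridian. An exactly
#' balanced antipodal configuration has no defined centroid and errors.
#'
#' @param points As in [dispersion_range()].
#' @return Named numeric `c(lon, lat)` in degrees.
#' @export
range_centroid <- function(points) {
  pts <- .as_points(points)
  .check_coords(pts$lon, pts$lat)
  torad <- pi / 180
  lam <- pts$lon * torad; phi <- pts$lat * torad
  v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)), mean(sin(phi)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("degenerate centroid")
  v <- v / nv
  c(lon = atan2(v[2], v[1]) / torad, lat = asin(v[3]) / torad)
}

#' Assign a biogeographic realm from a centroid and a lookup grid
#'
#' Point-in-polygon GIS is out of scope; instead the realm is read off a
#' user-supplied lookup table of grid-cell centres (columns `lon`, `lat`,
#' `region`). The centroid is matched to the nearest cell centre; if none
#' lies within `max_km`, the realm is `"Unknown"` with a warning (e.g. an
#' open-ocean centroid on a terrestrial grid).
#'
#' @param centroid Numeric `c(lon, lat)`.
#' @param lookup data.frame with columns `lon`, `lat`, `region`.
#' @param max_km Maximum great-circle distance to the nearest cell centre
#'   for a match (default 1000 km, generous for coarse grids).
#' @return Single realm name (character).
#' @export
assign_region <- function(centroid, lookup, max_km = 1000) {
  stopifnot(length(centroid) == 2L)
  .check_coords(centroid[1], centroid[2])
  if (!all(c("lon", "lat", "region") %in% names(lookup)))
    stop("lookup must have lon, lat, region columns")
  d <- haversine_km(centroid[1], centroid[2], lookup$lon, lookup$lat)
  i <- which.min(d)
  if (!length(i) || d[i] > max_km) {
    warning("centroid (", round(centroid[1], 2), ", ", round(centroid[2], 2),
            ") outside lookup coverage; region set to Unknown")
    return("Unknown")
  }
  as.character(lookup$region[i])
}

#' The eight biogeographic realms used for the crossed random intercept
#' @export
biogeographic_realms <- function() {
  c("Afrotropical", "Antarctic", "Australasian", "Nearctic",
    "Neotropical", "Oriental", "Pacific", "Palaearctic")
}
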