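#' Great-circle base-distance matrix
#'
#' Pairwise great-circle distances (haversine on a sphere) between two sets
#' of (longitude, latitude) points, in kilometres. This is the base distance
#' d_ij entering the transportation problem for surface maps: using geodesic
#' rather than Euclidean distance matters because grid cells can be far
#' apart on the sphere.
#'
#' @param coords_a data frame or matrix with columns `lon`, `lat`
#'   (degrees); rows are the source cells.
#' @param coords_b target cells, same format; defaults to `coords_a`.
#' @param radius_km sphere radius; default is the IUGG mean Earth radius
#'   6371.0088 km.
#' @return an `m x n` matrix of distances in km, with attribute
#'   `units = "km"`. Symmetric with an exactly zero diagonal when the two
#'   point sets coincide.
#' @export
great_circle_matrix <- function(coords_a, coords_b = coords_a,
                                radius_km = 6371.0088) {
  a <- as_lonlat(coords_a)
  b <- as_lonlat(coords_b)
  r_m <- radius_km * 1000
  d <- geosphere::distm(a, b,
                        fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = r_m))
  d <- d / 1000
  dimnames(d) <- NULL
  attr(d, "units") <- "km"
  d
}

as_lonlat <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("lon", "lat") %in% names(x))) {
    if (ncol(x) < 2) stop_validation("coordinates need lon and lat columns")
    names(x)[1:2] <- c("lon", "lat")
  }
  if (any(!is.finite(x$lon)) || any(!is.finite(x$lat)) ||
      any(x$lat < -90) || any(x$lat > 90))
    stop_validation("invalid coordinates")
  # wrap longitudes into [-180, 180): distances are invariant to +/- 360
  lon <- ((x$lon + 180) %% 360) - 180
  cbind(lon, x$lat)
}

#' Depth base-distance matrix
#'
#' Absolute depth differences in metres between two depth axes: the
#' one-dimensional base distance for comparing vertical profiles.
#'
#' @param axis_a,axis_b [depth_axis()] objects (or numeric depth vectors).
#' @return matrix of |z_i - z_j| in metres, attribute `units = "m"`.
#' @export
depth_distance_matrix <- function(axis_a, axis_b = axis_a) {
  za <- if (inherits(axis_a, "depth_axis")) axis_a$depths else as.numeric(axis_a)
  zb <- if (inherits(axis_b, "depth_axis")) axis_b$depths else as.numeric(axis_b)
  if (length(za) == 0L || length(zb) == 0L) stop_validation("depth axes must be nonempty")
  d <- abs(outer(za, zb, "-"))
  attr(d, "units") <- "m"
  d
}

#' Forbid long transport arcs
#'
#' Replaces base distances greater than a threshold by +Inf, restricting the
#' transport problem to local moves. Feasibility under the mask is checked
#' when the problem is solved.
#'
#' @param d base-distance matrix.
#' @param c threshold in the same units as `d`; arcs with `d > c` are
#'   forbidden.
#' @return the masked matrix (units attribute preserved).
#' @export
mask_long_arcs <- function(d, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop_validation("threshold c must be > 0")
  u <- attr(d, "units")
  d[d > c] <- Inf
  attr(d, "units") <- u
  d
}

# base-distance matrix between the supports of two probability fields
default_base_distance <- function(p, q, radius_km = 6371.0088) {
  if (p$kind != q$kind)
    stop_validation("cannot mix geographic and depth supports")
  if (p$kind == "geo") great_circle_matrix(p$coords, q$coords, radius_km = radius_km)
  else depth_distance_matrix(p$coords$depth, q$coords$depth)
}
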