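#' Regular longitude-latitude grid
#'
#' Defines the spatial support shared by all scalar fields in an analysis: a
#' regular grid of cell centres with a logical ocean mask. Cells are ordered
#' row-major by (latitude descending, longitude ascending); this order is
#' fixed so that transport plans and distance matrices are reproducible.
#'
#' @param lons numeric, distinct cell-centre longitudes in degrees east,
#'   in `[-180, 180)`.
#' @param lats numeric, distinct cell-centre latitudes in degrees north,
#'   in `[-90, 90]`.
#' @param mask logical matrix with `length(lats)` rows (latitude, descending)
#'   and `length(lons)` columns, `TRUE` for valid ocean cells. Default: all
#'   cells valid.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(lons, lats, mask = NULL) {
  lons <- sort(unique(as.numeric(lons)))
  lats <- sort(unique(as.numeric(lats)), decreasing = TRUE)
  if (any(lons < -180 | lons >= 180)) stop_validation("longitudes must lie in [-180, 180)")
  if (any(lats < -90 | lats > 90)) stop_validation("latitudes must lie in [-90, 90]")
  nlat <- length(lats); nlon <- length(lons)
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  mask <- matrix(as.logical(mask), nlat, nlon)
  if (!any(mask)) stop_validation("grid must have at least one valid cell")
  g <- structure(list(lons = lons, lats = lats, mask = mask,
                      nlon = nlon, nlat = nlat),
                 class = "grid_spec")
  g
}

# per-cell coordinates in canonical (lat desc, lon asc) row-major order
grid_coords_all <- function(grid) {
  data.frame(lon = rep(grid$lons, times = grid$nlat),
             lat = rep(grid$lats, each = grid$nlon))
}

# canonical row-major vector of the mask (and of any [nlat, nlon] matrix)
rowmajor <- function(m) as.vector(t(m))

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%d valid), lon [%g, %g], lat [%g, %g]\n",
              x$nlat, x$nlon, sum(x$mask),
              min(x$lons), max(x$lons), min(x$lats), max(x$lats)))
  invisible(x)
}

#' Gridded scalar field
#'
#' A non-negative concentration (e.g. chlorophyll-a in mg m^-3) on a
#' [grid_spec()]. Missing observations (clouds, dropouts) are `NA`; together
#' with the grid's land mask they are excluded from the support when the
#' field is normalized.
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `[nlat, nlon]` (latitude descending) or a
#'   vector in canonical cell order; `NA` marks missing cells.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- grid$nlat * grid$nlon
  if (is.matrix(values)) {
    if (nrow(values) != grid$nlat || ncol(values) != grid$nlon)
      stop_validation("values matrix must be [nlat, nlon]")
    values <- rowmajor(values)
  }
  if (length(values) != n) stop_validation("values length must equal nlat*nlon")
  values <- as.numeric(values)
  values[!rowmajor(grid$mask)] <- NA_real_
  ok <- !is.na(values)
  if (any(!is.finite(values[ok]))) stop_validation("values must be finite where present")
  if (any(values[ok] < 0)) stop_validation("negative values are not allowed")
  structure(list(grid = grid, values = values), class = "scalar_field")
}

# values as an [nlat, nlon] matrix
field_matrix <- function(field) {
  matrix(field$values, field$grid$nlat, field$grid$nlon, byrow = TRUE)
}

# indices (canonical order) of cells that are unmasked and observed
field_support <- function(field) {
  which(rowmajor(field$grid$mask) & !is.na(field$values))
}

#' @export
print.scalar_field <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("scalar_field on %d x %d grid: %d observed cells, range [%g, %g]\n",
              x$grid$nlat, x$grid$nlon, sum(ok),
              min(x$values[ok]), max(x$values[ok])))
  invisible(x)
}

#' Depth axis
#'
#' Strictly increasing depths (metres below surface) supporting a vertical
#' profile.
#'
#' @param depths numeric, non-negative, strictly increasing.
#' @return an object of class `depth_axis`.
#' @export
depth_axis <- function(depths) {
  depths <- as.numeric(depths)
  if (length(depths) < 1L) stop_validation("depth axis must be nonempty")
  if (any(depths < 0)) stop_validation("depths must be >= 0")
  if (any(diff(depths) <= 0)) stop_validation("depths must be strictly increasing")
  structure(list(depths = depths), class = "depth_axis")
}

#' @export
print.depth_axis <- function(x, ...) {
  cat(sprintf("depth_axis: %d depths, %g - %g m\n",
              length(x$depths), min(x$depths), max(x$depths)))
  invisible(x)
}

#' Vertical concentration profile
#'
#' A non-negative concentration per depth on a [depth_axis()]; the vertical
#' analogue of [scalar_field()].
#'
#' @param axis a [depth_axis()].
#' @param values numeric, one non-negative value per depth (`NA` = missing).
#' @return an object of class `depth_profile`.
#' @export
depth_profile <- function(axis, values) {
  stopifnot(inherits(axis, "depth_axis"))
  values <- as.numeric(values)
  if (length(values) != length(axis$depths))
    stop_validation("values length must match the depth axis")
  ok <- !is.na(values)
  if (any(!is.finite(values[ok]))) stop_validation("values must be finite where present")
  if (any(values[ok] < 0)) stop_validation("negative values are not allowed")
  structure(list(axis = axis, values = values), class = "depth_profile")
}

# internal constructor for normalized fields
new_probability_field <- function(probs, coords, kind, support = NULL,
                                  grid = NULL, axis = NULL) {
  structure(list(probs = probs, coords = coords, kind = kind,
                 support = support, grid = grid, axis = axis),
            class = "probability_field")
}

#' Normalize a field or profile to a discrete probability distribution
#'
#' Divides the non-negative values on the valid (unmasked, observed) cells by
#' their total so the result sums to one -- the normalization applied to
#' every map and profile before computing a Wasserstein distance. Masked and
#' missing cells are excluded from the support; observed zero-valued cells
#' remain in the support with probability zero.
#'
#' @param x a [scalar_field()] or [depth_profile()].
#' @return an object of class `probability_field` with elements `probs`
#'   (summing to 1), `coords` (a data frame of `lon`/`lat`, or `depth`),
#'   `kind` (`"geo"` or `"depth"`), and the originating grid or axis.
#' @export
normalize_field <- function(x) UseMethod("normalize_field")

#' @export
normalize_field.scalar_field <- function(x) {
  sup <- field_support(x)
  vals <- x$values[sup]
  if (any(vals < 0)) stop_validation("negative values are not allowed")
  total <- sum(vals)
  if (total <= 0) stop_validation("zero total mass: field has no positive values")
  co <- grid_coords_all(x$grid)[sup, , drop = FALSE]
  rownames(co) <- NULL
  new_probability_field(vals / total, co, "geo", support = sup, grid = x$grid)
}

#' @export
normalize_field.depth_profile <- function(x) {
  ok <- which(!is.na(x$values))
  if (length(ok) == 0L) stop_validation("zero total mass: profile is all missing")
  vals <- x$values[ok]
  total <- sum(vals)
  if (total <= 0) stop_validation("zero total mass: profile has no positive values")
  new_probability_field(vals / total,
                        data.frame(depth = x$axis$depths[ok]),
                        "depth", support = ok, axis = x$axis)
}

#' @export
normalize_field.probability_field <- function(x) x

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf("probability_field (%s): %d support cells, sum = %.15f\n",
              x$kind, length(x$probs), sum(x$probs)))
  invisible(x)
}

# check that two probability fields live on the exact same cells
same_support <- function(p, q, tol = 1e-9) {
  if (p$kind != q$kind) return(FALSE)
  if (length(p$probs) != length(q$probs)) return(FALSE)
  all(abs(as.matrix(p$coords) - as.matrix(q$coords)) <= tol)
}
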