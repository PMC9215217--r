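#' Estimate ocean provinces by K-means on a scalar field
#'
#' Clusters the per-cell scalar values (a one-dimensional feature; no
#' coordinates) into K provinces with seeded, multiply-restarted K-means.
#' Labels are renumbered so that cluster 1 has the lowest mean value, making
#' the labelling deterministic: in a two-province chlorophyll map, cluster 1
#' is the oligotrophic (low-chlorophyll) side.
#'
#' @param field a [scalar_field()].
#' @param K number of provinces, default 2.
#' @param seed RNG seed for the restarts (applied locally).
#' @param nstart K-means restarts, default 10.
#' @param log10_values cluster `log10(values)` instead of raw values
#'   (zero values are floored at the smallest positive value).
#' @return an object of class `province_labels`: the grid, the per-valid-cell
#'   labels, `K` and `seed`.
#' @export
kmeans_provinces <- function(field, K = 2, seed = 1L, nstart = 10,
                             log10_values = FALSE) {
  stopifnot(inherits(field, "scalar_field"))
  sup <- field_support(field)
  x <- field$values[sup]
  if (log10_values) {
    pos <- x[x > 0]
    if (length(pos) == 0L) stop_validation("degenerate clustering: no positive values")
    x <- log10(pmax(x, min(pos)))
  }
  if (length(unique(x)) < K)
    stop_validation("degenerate clustering: fewer than K distinct values")
  km <- with_seed(seed, kmeans(x, centers = K, nstart = nstart, iter.max = 200))
  # renumber so cluster means are increasing
  ord <- order(km$centers[, 1])
  relab <- integer(K); relab[ord] <- seq_len(K)
  labels <- relab[km$cluster]
  structure(list(grid = field$grid, support = sup, labels = labels,
                 K = K, seed = seed,
                 centers = sort(km$centers[, 1])),
            class = "province_labels")
}

#' @export
print.province_labels <- function(x, ...) {
  cat(sprintf("province_labels: K = %d over %d cells; sizes %s; centers %s\n",
              x$K, length(x$labels),
              paste(tabulate(x$labels, x$K), collapse = "/"),
              paste(signif(x$centers, 4), collapse = ", ")))
  invisible(x)
}

#' Extract the discretized province boundary as a probability field
#'
#' Boundary cells are the valid cells with at least one 4-neighbour (north,
#' south, east, west on the grid) carrying a different province label --
#' both sides of each interface, so the boundary is invariant to relabelling
#' the provinces. Each boundary cell gets uniform mass 1/(number of boundary
#' cells): the "binary field that is zero inside the provinces and a nonzero
#' constant along the boundaries", normalized.
#'
#' @param labels a [kmeans_provinces()] result.
#' @return a [probability_field] supported on the boundary cells.
#' @export
boundary_field <- function(labels) {
  stopifnot(inherits(labels, "province_labels"))
  if (length(unique(labels$labels)) < 2L)
    stop_validation("no boundary: fewer than two nonempty provinces")
  g <- labels$grid
  # labels back onto the [nlat, nlon] grid via the canonical row-major order
  full <- rep(NA_integer_, g$nlat * g$nlon)
  full[labels$support] <- labels$labels
  lab <- matrix(full, g$nlat, g$nlon, byrow = TRUE)
  differs <- function(a, b) !is.na(a) & !is.na(b) & a != b
  bnd <- matrix(FALSE, g$nlat, g$nlon)
  if (g$nlat > 1) {
    up <- differs(lab[-1, , drop = FALSE], lab[-g$nlat, , drop = FALSE])
    bnd[-1, ] <- bnd[-1, ] | up
    bnd[-g$nlat, ] <- bnd[-g$nlat, ] | up
  }
  if (g$nlon > 1) {
    lr <- differs(lab[, -1, drop = FALSE], lab[, -g$nlon, drop = FALSE])
    bnd[, -1] <- bnd[, -1] | lr
    bnd[, -g$nlon] <- bnd[, -g$nlon] | lr
  }
  cells <- which(rowmajor(bnd) & !is.na(full))
  if (length(cells) == 0L)
    stop_validation("no boundary: provinces are not adjacent on the grid")
  co <- grid_coords_all(g)[cells, , drop = FALSE]
  rownames(co) <- NULL
  new_probability_field(rep(1 / length(cells), length(cells)), co, "geo",
                        support = cells, grid = g)
}

#' Wasserstein distance between the province boundaries of two maps
#'
#' Clusters each map into K provinces, extracts the discretized boundary
#' fields and measures the transport needed to move one boundary onto the
#' other -- a feature-level comparison that ignores within-province value
#' differences.
#'
#' @param field_a,field_b [scalar_field()] maps on a common grid (the grids
#'   may differ; boundaries are compared by great-circle distance between
#'   boundary cells).
#' @param K number of provinces, default 2.
#' @param seeds length-2 seeds for the two clusterings.
#' @param d optional base-distance matrix between the *full* supports of the
#'   two grids; the boundary-cell submatrix is extracted from it. Computed
#'   directly between boundary cells when omitted.
#' @param ... passed to [kmeans_provinces()].
#' @return list with `w2` (km), the transport `plan`, and the two
#'   `boundaries`.
#' @export
boundary_distance <- function(field_a, field_b, K = 2, seeds = c(1L, 1L),
                              d = NULL, ...) {
  la <- kmeans_provinces(field_a, K = K, seed = seeds[1], ...)
  lb <- kmeans_provinces(field_b, K = K, seed = seeds[2], ...)
  ba <- boundary_field(la)
  bb <- boundary_field(lb)
  dsub <- if (is.null(d)) great_circle_matrix(ba$coords, bb$coords)
          else { s <- d[ba$support, bb$support, drop = FALSE]; attr(s, "units") <- attr(d, "units"); s }
  plan <- solve_transport(ba, bb, d = dsub)
  list(w2 = plan$w2, plan = plan, boundaries = list(a = ba, b = bb),
       labels = list(a = la, b = lb))
}
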