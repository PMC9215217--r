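# CSV readers/writers. Numeric output uses 17 significant digits so that
# write -> read round-trips are bit-stable.

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_table17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt17)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Read a gridded field from CSV
#'
#' Expects columns `lon`, `lat`, `value`. The grid is reconstructed from the
#' unique coordinates; cells absent from the file and cells with `NA` value
#' are masked.
#'
#' @param path CSV file.
#' @return a [scalar_field()].
#' @export
read_field_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("lon", "lat", "value") %in% names(df)))
    stop_validation("field CSV needs columns lon, lat, value")
  g <- grid_spec(unique(df$lon), unique(df$lat))
  full <- rep(NA_real_, g$nlat * g$nlon)
  co <- grid_coords_all(g)
  key <- paste(co$lon, co$lat)
  idx <- match(paste(df$lon, df$lat), key)
  if (anyNA(idx)) stop_validation("field CSV coordinates do not form a regular grid")
  full[idx] <- df$value
  g$mask <- matrix(!is.na(full), g$nlat, g$nlon, byrow = TRUE)
  scalar_field(g, full)
}

#' Write a gridded field to CSV (lon, lat, value; masked cells omitted)
#' @param field a [scalar_field()].
#' @param path output file.
#' @export
write_field_csv <- function(field, path) {
  sup <- field_support(field)
  co <- grid_coords_all(field$grid)[sup, , drop = FALSE]
  write_table17(data.frame(co, value = field$values[sup]), path)
  invisible(path)
}

#' Read depth samples or a profile from CSV (columns date, depth, value)
#' @param path CSV file; a missing `date` column is tolerated for plain
#'   profiles.
#' @return data frame `date, depth, value`.
#' @export
read_samples_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("depth", "value") %in% names(df)))
    stop_validation("samples CSV needs columns depth, value")
  if (!"date" %in% names(df)) df$date <- NA
  df[c("date", "depth", "value")]
}

#' Read/write a labelled distance matrix as CSV
#' @param path CSV file; first column holds the labels.
#' @return an `omd_distmat`.
#' @export
read_distance_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  M <- as.matrix(df[-1])
  dimnames(M) <- list(labels, labels)
  structure(M, class = c("omd_distmat", "matrix", "array"))
}

#' @rdname read_distance_matrix_csv
#' @param D an `omd_distmat` or plain symmetric matrix.
#' @export
write_distance_matrix_csv <- function(D, path) {
  D <- as.matrix(D)
  df <- data.frame(label = rownames(D) %||% as.character(seq_len(nrow(D))),
                   D, check.names = FALSE)
  names(df)[-1] <- rownames(D) %||% as.character(seq_len(nrow(D)))
  write_table17(df, path)
  invisible(path)
}

#' Write an MDS embedding as CSV (label, coordinates, eigenvalue share)
#' @param mds an [classical_mds()] result.
#' @param path output file.
#' @export
write_mds_csv <- function(mds, path) {
  share <- mds$eig_clamped / sum(mds$eig_clamped)
  df <- data.frame(label = rownames(mds$points) %||%
                     as.character(seq_len(nrow(mds$points))),
                   mds$points)
  for (k in seq_len(ncol(mds$points)))
    df[[paste0("eig_share", k)]] <- share[k]
  write_table17(df, path)
  invisible(path)
}

#' Export a transport plan as CSV
#'
#' Columns `i, j`, the endpoint coordinates, `mass` and the arc length.
#'
#' @param plan a [solve_transport()] result.
#' @param path output file.
#' @export
write_plan_csv <- function(plan, path) {
  ts <- transport_summary(plan, drop_zero_dist = FALSE)
  df <- cbind(plan$arcs[c("i", "j")], ts[setdiff(names(ts), c("i", "j"))])
  write_table17(df, path)
  invisible(path)
}

#' Export a transport plan as GeoJSON LineStrings
#'
#' One feature per mass-moving arc with `mass` and `dist` properties; for
#' arrow plots in GIS tools. Geographic plans only.
#'
#' @param plan a [solve_transport()] result on geographic supports.
#' @param path output file.
#' @export
write_plan_geojson <- function(plan, path) {
  if (is.null(plan$source) || plan$source$kind != "geo")
    stop_validation("GeoJSON export requires a geographic plan")
  ts <- transport_summary(plan)
  feats <- lapply(seq_len(nrow(ts)), function(k) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(ts$lon_i[k], ts$lat_i[k]),
                                            c(ts$lon_j[k], ts$lat_j[k]))),
         properties = list(mass = ts$mass[k], dist = ts$dist[k]))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write province labels as CSV (lon, lat, label)
#' @param labels a [kmeans_provinces()] result.
#' @param path output file.
#' @export
write_labels_csv <- function(labels, path) {
  co <- grid_coords_all(labels$grid)[labels$support, , drop = FALSE]
  write_table17(data.frame(co, label = labels$labels), path)
  invisible(path)
}
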