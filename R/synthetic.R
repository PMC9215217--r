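#' Regular grid over a lon/lat box
#'
#' Convenience constructor for the synthetic experiments.
#'
#' @param lon_range,lat_range length-2 numeric ranges (degrees).
#' @param res cell size in degrees.
#' @export
make_grid <- function(lon_range = c(-180, -100), lat_range = c(-30, 10),
                      res = 2.5) {
  grid_spec(seq(lon_range[1], lon_range[2], by = res),
            seq(lat_range[1], lat_range[2], by = res))
}

#' Smooth latitudinal background field
#'
#' A deterministic logistic front in latitude: low chlorophyll on the
#' equatorward plateau rising to a high poleward plateau, emulating the
#' strong meridional gradient across a transition zone. With
#' `high == low` the field is constant.
#'
#' @param grid a [grid_spec()].
#' @param low,high plateau concentrations (mg m^-3).
#' @param front_lat latitude of the front midpoint (where the value is the
#'   midpoint of the plateaus); default the grid's central latitude.
#' @param width_deg logistic width in degrees.
#' @return a [scalar_field()], monotone along every meridian.
#' @export
make_background <- function(grid, low = 0.05, high = 1,
                            front_lat = mean(range(grid$lats)),
                            width_deg = 5) {
  co <- grid_coords_all(grid)
  v <- low + (high - low) / (1 + exp(-(co$lat - front_lat) / width_deg))
  scalar_field(grid, v)
}

#' Gaussian patch specification
#'
#' @param center `c(lon, lat)` of the patch centre (degrees).
#' @param amplitude peak concentration added (mg m^-3).
#' @param width_km Gaussian standard deviation (km).
#' @param aspect ratio of the along/across widths (1 = circular).
#' @param rotation_deg patch rotation (only meaningful when `aspect != 1`);
#'   default 0 (off).
#' @export
patch_spec <- function(center, amplitude = 1, width_km = 550,
                       aspect = 1, rotation_deg = 0) {
  if (amplitude <= 0 || width_km <= 0) stop_validation("amplitude and width must be > 0")
  structure(list(center = center, amplitude = amplitude, width_km = width_km,
                 aspect = aspect, rotation_deg = rotation_deg),
            class = "patch_spec")
}

# Gaussian bump values on the grid, local tangent-plane approximation
patch_values <- function(grid, patch, radius_km = 6371.0088) {
  co <- grid_coords_all(grid)
  kmdeg <- pi * radius_km / 180
  dx <- (co$lon - patch$center[1]) * cos(patch$center[2] * pi / 180) * kmdeg
  dy <- (co$lat - patch$center[2]) * kmdeg
  th <- patch$rotation_deg * pi / 180
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  patch$amplitude * exp(-0.5 * ((xr / patch$width_km)^2 +
                                (yr / (patch$width_km * patch$aspect))^2))
}

#' Background plus an eastward-shifting Gaussian patch
#'
#' The toy experiment: a fixed background with an added patch whose centre
#' is displaced east by each of `shifts_deg`. Comparing the unshifted field
#' with each shifted one shows the saturation contrast -- RMSE plateaus once
#' patch supports stop overlapping while W2 keeps growing linearly with the
#' displacement.
#'
#' @param background a [scalar_field()].
#' @param patch a [patch_spec()].
#' @param shifts_deg longitude offsets in degrees (e.g. `seq(0, 40, 5)`).
#' @param rotate_deg_per_shift optional rotation added per shifted field;
#'   default 0 (off).
#' @return named list of [scalar_field()]s (`shift_0`, `shift_5`, ...), with
#'   attribute `"centers"` (patch centres per field).
#' @export
make_patch_series <- function(background, patch, shifts_deg = seq(0, 40, by = 5),
                              rotate_deg_per_shift = 0) {
  g <- background$grid
  centers <- data.frame(lon = patch$center[1] + shifts_deg,
                        lat = rep(patch$center[2], length(shifts_deg)))
  if (any(centers$lon < min(g$lons) | centers$lon > max(g$lons)))
    stop_validation("patch off-grid: a shifted centre leaves the longitude range")
  fields <- lapply(seq_along(shifts_deg), function(k) {
    p <- patch
    p$center <- c(centers$lon[k], centers$lat[k])
    p$rotation_deg <- patch$rotation_deg + rotate_deg_per_shift * shifts_deg[k]
    scalar_field(g, background$values + patch_values(g, p))
  })
  names(fields) <- paste0("shift_", shifts_deg)
  attr(fields, "centers") <- centers
  attr(fields, "shifts_deg") <- shifts_deg
  fields
}

#' Distance curves for a patch series
#'
#' The canonical saturation experiment (run by default on a 2.5-degree
#' Pacific box with the chlorophyll front along the domain's northern
#' section and the patch on the low-chlorophyll plateau at (-150, -15)):
#' compares the unshifted field with each shifted one by both W2 and RMSE
#' and reports them against the great-circle displacement of the patch
#' centre. Expected behaviour: RMSE saturates once the patch supports stop
#' overlapping (displacement beyond about 4 Gaussian widths), while W2 keeps
#' growing close to linearly with the displacement.
#'
#' @param fields a [make_patch_series()] result; built from the defaults
#'   when omitted.
#' @return data frame `shift_deg`, `shift_km`, `w2`, `rmse` (one row per
#'   shifted field, the unshifted reference excluded).
#' @export
patch_distance_curve <- function(fields = NULL) {
  if (is.null(fields)) {
    grid <- make_grid()
    bg <- make_background(grid, front_lat = 5)
    fields <- make_patch_series(bg, patch_spec(c(-150, -15)))
  }
  centers <- attr(fields, "centers")
  shifts <- attr(fields, "shifts_deg")
  if (is.null(centers)) stop_validation("fields must come from make_patch_series")
  pf <- lapply(fields, normalize_field)
  d <- great_circle_matrix(pf[[1]]$coords, pf[[1]]$coords)
  shift_km <- great_circle_matrix(centers[1, , drop = FALSE], centers)[1, ]
  out <- data.frame(shift_deg = shifts[-1], shift_km = shift_km[-1],
                    w2 = vapply(seq_along(pf)[-1], function(k)
                      solve_transport(pf[[1]], pf[[k]], d = d)$w2, numeric(1)),
                    rmse = vapply(seq_along(pf)[-1], function(k)
                      rmse(pf[[1]], pf[[k]]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Dated series of maps with a seasonally moving blob and optional drift
#'
#' A test bed for the seasonal-trend regression: a Gaussian blob on a fixed
#' background whose centre longitude follows an annual sinusoid, plus an
#' optional linear drift and seeded positional noise. With zero drift and
#' noise the series is exactly 12-month periodic, so same-calendar-month
#' maps coincide; a positive drift makes maps drift apart linearly in time.
#'
#' @param grid a [grid_spec()].
#' @param months number of monthly fields.
#' @param start `c(year, month)` of the first field.
#' @param center `c(lon, lat)` base blob centre.
#' @param seasonal_amplitude_km annual displacement amplitude.
#' @param drift_km_per_month long-term drift rate of the blob centre.
#' @param noise_km standard deviation of seeded positional jitter.
#' @param seed RNG seed (applied locally; same seed, same series).
#' @param patch blob shape, a [patch_spec()] (its centre is overridden).
#' @param background background field; defaults to a constant low field on
#'   `grid`.
#' @return list with `fields` (named list of [scalar_field()]) and `dates`
#'   (data frame `year`, `month`).
#' @export
make_seasonal_series <- function(grid, months = 48, start = c(1998, 1),
                                 center = c(-150, -12),
                                 seasonal_amplitude_km = 800,
                                 drift_km_per_month = 0,
                                 noise_km = 0, seed = 1L,
                                 patch = patch_spec(center, amplitude = 1,
                                                    width_km = 400),
                                 background = make_background(grid, low = 0.1,
                                                              high = 0.1)) {
  t <- seq_len(months) - 1L
  mon <- ((start[2] - 1 + t) %% 12) + 1L
  yr <- start[1] + (start[2] - 1 + t) %/% 12
  jitter <- if (noise_km > 0) with_seed(seed, stats::rnorm(months, 0, noise_km))
            else numeric(months)
  kmdeg <- pi * 6371.0088 / 180 * cos(center[2] * pi / 180)
  dx_km <- seasonal_amplitude_km * sin(2 * pi * (mon - 1) / 12) +
    drift_km_per_month * t + jitter
  lons <- center[1] + dx_km / kmdeg
  if (any(lons < min(grid$lons) | lons > max(grid$lons)))
    stop_validation("patch off-grid: blob centre leaves the longitude range")
  fields <- lapply(seq_len(months), function(k) {
    p <- patch
    p$center <- c(lons[k], center[2])
    scalar_field(grid, background$values + patch_values(grid, p))
  })
  names(fields) <- sprintf("%04d-%02d", yr, mon)
  list(fields = fields, dates = data.frame(year = yr, month = mon))
}

#' Synthetic depth profile with a controllable chlorophyll maximum
#'
#' A Gaussian peak at `dcm_depth` over a small surface baseline, normalized
#' to a probability profile; optional seeded additive noise (clamped at
#' zero). As `surface_level` and `width_m` shrink the profile approaches a
#' point mass at the peak.
#'
#' @param axis a [depth_axis()].
#' @param dcm_depth peak depth (m), within the axis range.
#' @param width_m Gaussian width (m).
#' @param surface_level baseline relative to the unit peak.
#' @param noise additive noise s.d. relative to the unit peak.
#' @param seed RNG seed for the noise (applied locally).
#' @return a [probability_field] on `axis`.
#' @export
make_profile <- function(axis, dcm_depth, width_m = 20, surface_level = 0.1,
                         noise = 0, seed = 1L) {
  stopifnot(inherits(axis, "depth_axis"))
  z <- axis$depths
  if (dcm_depth < min(z) || dcm_depth > max(z))
    stop_validation("dcm_depth outside the axis range")
  v <- surface_level + exp(-0.5 * ((z - dcm_depth) / width_m)^2)
  if (noise > 0)
    v <- pmax(v + with_seed(seed, stats::rnorm(length(z), 0, noise)), 0)
  normalize_field(depth_profile(axis, v))
}

#' Translate a profile along its depth axis
#'
#' Shifts the probability vector by a whole number of axis steps (the axis
#' must be uniformly spaced), producing an exact discrete translate: the
#' 2-Wasserstein distance between a profile and its translate equals the
#' shift exactly. Errors if any mass would be pushed off the axis.
#'
#' @param profile a [probability_field] on a depth axis.
#' @param shift_m shift in metres, a multiple of the axis spacing
#'   (positive = deeper).
#' @return the translated [probability_field].
#' @export
shift_profile <- function(profile, shift_m) {
  profile <- normalize_field(profile)
  if (profile$kind != "depth") stop_validation("profile must live on a depth axis")
  z <- profile$coords$depth
  dz <- diff(z)
  if (max(dz) - min(dz) > 1e-9) stop_validation("axis must be uniformly spaced")
  step <- dz[1]
  k <- shift_m / step
  if (abs(k - round(k)) > 1e-9)
    stop_validation("shift must be a multiple of the axis spacing")
  k <- as.integer(round(k))
  n <- length(z)
  if (abs(k) >= n) stop_validation("shift exceeds the axis range")
  p <- profile$probs
  out <- rep(0, n)
  if (k >= 0) {
    if (k > 0 && any(p[seq.int(n - k + 1L, n)] > 0))
      stop_validation("shift pushes mass off the bottom of the axis")
    out[seq.int(1L + k, n)] <- p[seq_len(n - k)]
  } else {
    if (any(p[seq_len(-k)] > 0))
      stop_validation("shift pushes mass off the top of the axis")
    out[seq_len(n + k)] <- p[seq.int(1L - k, n)]
  }
  pf <- profile
  pf$probs <- out
  pf
}
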