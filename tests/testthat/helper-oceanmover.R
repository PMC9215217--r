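# shared fixture builders (everything generated in code, no data files)

# random discrete distribution of length n (strictly positive)
rand_prob <- function(n) {
  p <- runif(n) + 1e-3
  p / sum(p)
}

# random geographic support: n points spread over the mid-latitudes
rand_geo_coords <- function(n) {
  data.frame(lon = runif(n, -180, 179.9), lat = runif(n, -60, 60))
}

# probability field on an explicit geographic support (bypasses gridding)
geo_prob_field <- function(probs, coords) {
  oceanmover:::new_probability_field(probs, coords, "geo")
}

# point-mass profile on a shared axis
point_profile <- function(axis, depth) {
  v <- rep(0, length(axis$depths))
  v[which.min(abs(axis$depths - depth))] <- 1
  normalize_field(depth_profile(axis, v))
}

# compactly supported triangular bump (an exact translate under shifting)
triangle_profile <- function(axis, peak, halfwidth = 30) {
  v <- pmax(1 - abs(axis$depths - peak) / halfwidth, 0)
  normalize_field(depth_profile(axis, v))
}

# random profile with positive mass everywhere
rand_profile <- function(axis) {
  normalize_field(depth_profile(axis, runif(length(axis$depths)) + 0.01))
}

# small two-block field: low values south of split_lat, high north of it
split_field <- function(grid, split_lat, low = 0.1, high = 1.0) {
  co <- oceanmover:::grid_coords_all(grid)
  scalar_field(grid, ifelse(co$lat > split_lat, high, low))
}

# check a plan's marginals against its inputs
max_marginal_error <- function(plan, p, q) {
  pv <- if (inherits(p, "probability_field")) p$probs else p
  qv <- if (inherits(q, "probability_field")) q$probs else q
  rs <- rep(0, length(pv)); cs <- rep(0, length(qv))
  agg <- tapply(plan$arcs$mass, plan$arcs$i, sum)
  rs[as.integer(names(agg))] <- agg
  agg <- tapply(plan$arcs$mass, plan$arcs$j, sum)
  cs[as.integer(names(agg))] <- agg
  max(abs(rs - pv / sum(pv)), abs(cs - qv / sum(qv)))
}

# noiseless distance matrix following the seasonal-trend model
trend_distmat <- function(dates, beta0, beta1, beta2) {
  N <- nrow(dates)
  D <- matrix(0, N, N)
  for (a in seq_len(N - 1)) for (b in seq.int(a + 1, N)) {
    f <- month_lag_features(c(dates$year[a], dates$month[a]),
                            c(dates$year[b], dates$month[b]))
    D[a, b] <- D[b, a] <- beta0 + beta1 * f$total_lag + beta2[f$calendar_lag + 1]
  }
  D
}

# monthly date table spanning `years` full years
month_dates <- function(years = 1998:2000) {
  expand.grid(month = 1:12, year = years)[, c("year", "month")]
}
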