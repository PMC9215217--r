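#' Month-lag features for a pair of dated maps
#'
#' For maps dated (year, month), the trend regression uses two predictors:
#' the total number of months apart (year-aware), and the circular
#' calendar-month distance ignoring years, folded to `{0, ..., 6}`.
#'
#' @param a,b length-2 vectors `c(year, month)`.
#' @return list with `total_lag` and `calendar_lag`.
#' @export
month_lag_features <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (a[2] < 1 || a[2] > 12 || b[2] < 1 || b[2] > 12)
    stop_validation("months must be in 1..12")
  total <- abs(12 * (a[1] - b[1]) + (a[2] - b[2]))
  dm <- abs(a[2] - b[2])
  list(total_lag = total, calendar_lag = min(dm, 12 - dm))
}

# upper-triangle pair table with lag features
pair_lag_table <- function(D, dates) {
  N <- nrow(D)
  stopifnot(nrow(dates) == N)
  a <- rep(seq_len(N - 1L), times = (N - 1L):1L)
  b <- unlist(lapply(seq_len(N - 1L), function(i) seq.int(i + 1L, N)))
  ym <- 12 * dates$year + dates$month
  total <- abs(ym[a] - ym[b])
  dm <- abs(dates$month[a] - dates$month[b])
  data.frame(a = a, b = b, y = D[cbind(a, b)],
             total_lag = total, calendar_lag = pmin(dm, 12 - dm))
}

#' Fit the seasonal-trend regression of pairwise distances on month lags
#'
#' Models the distance `D_ab` between maps dated (year, month) as
#'
#'   `beta0 + beta1 * |ym(a) - ym(b)| + sum_k beta2_k 1(|m(a) - m(b)| = k)`
#'
#' with the seasonal coefficients over calendar lags `k = 0..6` constrained
#' to sum to zero, fitted by ordinary least squares on all `N(N-1)/2`
#' upper-triangle pairs. `beta1` is the long-term trend in distance per month
#' of separation once the annual cycle is accounted for; the trend line
#' (`beta0 + beta1 * lag`) is the fit stripped of the seasonal term.
#'
#' The sum-to-zero constraint is imposed through a reparameterized design;
#' when some calendar-lag levels do not occur in the data, the constraint is
#' applied over the levels present (absent levels get coefficient zero and
#' are recorded in `$absent_lags`). Pairs are treated as independent
#' observations, as is conventional for this regression; standard errors do
#' not account for the dependence among pairs sharing a map.
#'
#' @param D symmetric distance matrix over the dated maps.
#' @param dates data frame with integer columns `year` and `month`
#'   (1..12), one row per row of `D`.
#' @return an object of class `seasonal_trend_fit` with coefficients
#'   `beta0`, `beta1`, `beta2` (length 7, named `lag0..lag6`, summing to
#'   zero), standard errors, `sigma`, `r.squared`, the pair table, and the
#'   underlying `lm` fit.
#' @seealso [slope_ratio()], [month_lag_features()]
#' @export
fit_seasonal_trend <- function(D, dates) {
  D <- as.matrix(D)
  dates <- as.data.frame(dates)
  if (!all(c("year", "month") %in% names(dates)))
    stop_validation("dates needs columns year and month")
  if (any(dates$month < 1 | dates$month > 12)) stop_validation("months must be in 1..12")
  tab <- pair_lag_table(D, dates)
  if (nrow(tab) < 9L) stop_validation("need at least 9 unique pairs")
  lev <- sort(unique(tab$calendar_lag))
  absent <- setdiff(0:6, lev)
  if (length(lev) < 2L)
    stop_validation("rank-deficient design: only calendar lag ",
                    paste(lev, collapse = ","), " present; missing lags ",
                    paste(absent, collapse = ","))
  p <- length(lev)
  # sum-to-zero reparameterization over present levels: p-1 columns
  Z <- matrix(0, nrow(tab), p - 1L,
              dimnames = list(NULL, paste0("s", lev[-p])))
  for (r in seq_len(p - 1L)) Z[tab$calendar_lag == lev[r], r] <- 1
  Z[tab$calendar_lag == lev[p], ] <- -1
  df <- data.frame(y = tab$y, total_lag = tab$total_lag, Z)
  fit <- lm(y ~ ., data = df)
  if (fit$rank < ncol(df))
    stop_validation("rank-deficient design (total lag confounded with the ",
                    "seasonal indicators); missing calendar lags: ",
                    if (length(absent)) paste(absent, collapse = ",") else "none")
  cf <- coef(fit)
  gam <- cf[-(1:2)]
  beta2 <- numeric(7)
  names(beta2) <- paste0("lag", 0:6)
  beta2[lev[-p] + 1L] <- gam
  beta2[lev[p] + 1L] <- -sum(gam)
  # standard errors of the reconstructed seasonal coefficients ("essentially
  # perfect fit" warnings are expected on noiseless synthetic input)
  V <- suppressWarnings(vcov(fit))
  se2 <- rep(NA_real_, 7)
  gi <- seq.int(3, length(cf))
  for (r in seq_len(p - 1L)) se2[lev[r] + 1L] <- sqrt(V[gi[r], gi[r]])
  Lp <- rep(-1, p - 1L)
  se2[lev[p] + 1L] <- sqrt(drop(t(Lp) %*% V[gi, gi, drop = FALSE] %*% Lp))
  s <- suppressWarnings(summary(fit))
  structure(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]), beta2 = beta2,
                 se = list(beta0 = s$coefficients[1, 2],
                           beta1 = s$coefficients[2, 2],
                           beta2 = se2),
                 sigma = s$sigma, r.squared = s$r.squared,
                 pairs = tab, levels_present = lev, absent_lags = absent,
                 lm = fit),
            class = "seasonal_trend_fit")
}

#' @export
coef.seasonal_trend_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, object$beta2)
}

#' @export
print.seasonal_trend_fit <- function(x, ...) {
  cat("seasonal-trend fit of pairwise distances on month lags\n")
  cat(sprintf("  trend:    beta0 = %.6g, beta1 = %.6g per month (SE %.3g)\n",
              x$beta0, x$beta1, x$se$beta1))
  cat("  seasonal (sum-to-zero):\n")
  print(round(x$beta2, 6))
  if (length(x$absent_lags))
    cat("  calendar lags absent from data (coefficient fixed at 0): ",
        paste(x$absent_lags, collapse = ","), "\n")
  cat(sprintf("  R^2 = %.4f on %d pairs\n", x$r.squared, nrow(x$pairs)))
  invisible(x)
}

#' @export
summary.seasonal_trend_fit <- function(object, ...) {
  print(object)
  cat("\nunderlying least-squares fit:\n")
  print(summary(object$lm)$coefficients)
  invisible(object)
}

#' Predicted distance for pairs of dates
#'
#' @param object a [fit_seasonal_trend()] result.
#' @param newdata data frame with columns `total_lag` and `calendar_lag`
#'   (or omitted, for fitted values on the training pairs).
#' @param seasonal include the seasonal term (`TRUE`, the full model) or
#'   only the linear trend (`FALSE`).
#' @param ... unused.
#' @export
predict.seasonal_trend_fit <- function(object, newdata = NULL,
                                       seasonal = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$pairs
  out <- object$beta0 + object$beta1 * newdata$total_lag
  if (seasonal) out <- out + object$beta2[newdata$calendar_lag + 1L]
  unname(out)
}

#' @export
fitted.seasonal_trend_fit <- function(object, ...) predict(object)

#' @export
residuals.seasonal_trend_fit <- function(object, ...) {
  object$pairs$y - predict(object)
}

#' Ratio of trend slopes between two fits
#'
#' `beta1_A / beta1_B`: how many times faster distances grow with time in
#' source A than in source B (e.g. remote sensing versus model).
#'
#' @param fit_a,fit_b [fit_seasonal_trend()] results.
#' @return scalar ratio; `NA` with a warning when the denominator slope is
#'   zero, and a warning when it is negative.
#' @export
slope_ratio <- function(fit_a, fit_b) {
  b1a <- fit_a$beta1; b1b <- fit_b$beta1
  if (b1b == 0) {
    warning("denominator slope is zero; ratio undefined")
    return(NA_real_)
  }
  if (b1b < 0) warning("denominator slope is negative; ratio sign flipped")
  b1a / b1b
}

#' Distance of each dated field to a reference field
#'
#' The time-series view: the Wasserstein or RMSE distance from one reference
#' map (e.g. January of the first year) to every other map in a dated
#' collection, optionally min-max normalized to [0, 1] to compare the two
#' metrics' seasonal phase.
#'
#' @param fields list of fields (normalized internally).
#' @param dates data frame `year`, `month` per field.
#' @param reference index or label of the reference field.
#' @param metric `"wasserstein"` or `"rmse"`.
#' @param d optional shared base-distance matrix.
#' @param normalize min-max normalize distances to `[0, 1]`.
#' @return data frame `year`, `month`, `distance`; attribute `"peaks"` holds
#'   the peak month per year.
#' @export
reference_distance_series <- function(fields, dates, reference = 1L,
                                      metric = c("wasserstein", "rmse"),
                                      d = NULL, normalize = FALSE) {
  metric <- match.arg(metric)
  fields <- lapply(fields, normalize_field)
  if (is.character(reference)) reference <- match(reference, names(fields))
  if (is.na(reference) || reference < 1 || reference > length(fields))
    stop_validation("reference not found in the collection")
  ref <- fields[[reference]]
  if (metric == "wasserstein" && is.null(d) &&
      all(vapply(fields, function(f) same_support(ref, f), logical(1))))
    d <- default_base_distance(ref, ref)
  dist <- vapply(fields, function(f) {
    if (metric == "rmse") rmse(ref, f) else solve_transport(ref, f, d = d)$w2
  }, numeric(1))
  if (normalize) {
    rng <- range(dist)
    dist <- if (diff(rng) > 0) (dist - rng[1]) / diff(rng) else dist * 0
  }
  out <- data.frame(year = dates$year, month = dates$month, distance = dist)
  rownames(out) <- NULL
  peaks <- do.call(rbind, lapply(split(out, out$year), function(g) {
    g[which.max(g$distance), c("year", "month"), drop = FALSE]
  }))
  rownames(peaks) <- NULL
  attr(out, "peaks") <- peaks
  out
}
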