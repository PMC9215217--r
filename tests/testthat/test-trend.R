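test_that("month-lag features are year-aware and circularly folded", {
  expect_equal(month_lag_features(c(1998, 1), c(1998, 3)),
               list(total_lag = 2, calendar_lag = 2))
  expect_equal(month_lag_features(c(1998, 1), c(1998, 12)),
               list(total_lag = 11, calendar_lag = 1))
  expect_equal(month_lag_features(c(2000, 6), c(2000, 6)),
               list(total_lag = 0, calendar_lag = 0))
  expect_equal(month_lag_features(c(1998, 1), c(2000, 7))$calendar_lag, 6)
  expect_equal(month_lag_features(c(2001, 2), c(1998, 11)),
               list(total_lag = 27, calendar_lag = 3))
})

test_that("noiseless seasonal-trend data is recovered exactly", {
  dates <- month_dates(1998:2000)
  beta2 <- c(0.2, 0.1, 0, -0.05, -0.1, -0.1, -0.05)
  D <- trend_distmat(dates, beta0 = 1, beta1 = 0.01, beta2 = beta2)
  fit <- fit_seasonal_trend(D, dates)
  expect_equal(fit$beta0, 1, tolerance = 1e-8)
  expect_equal(fit$beta1, 0.01, tolerance = 1e-8)
  expect_equal(unname(fit$beta2), beta2, tolerance = 1e-8)
  expect_lt(abs(sum(fit$beta2)), 1e-10)

  # constant distances: no trend, no seasonality
  Dc <- trend_distmat(dates, 2, 0, rep(0, 7))
  fitc <- fit_seasonal_trend(Dc, dates)
  expect_equal(fitc$beta1, 0, tolerance = 1e-10)
  expect_equal(max(abs(fitc$beta2)), 0, tolerance = 1e-10)

  # pure trend
  Dt <- trend_distmat(dates, 0, 0.01, rep(0, 7))
  fitt <- fit_seasonal_trend(Dt, dates)
  expect_equal(fitt$beta1, 0.01, tolerance = 1e-10)
  expect_equal(max(abs(fitt$beta2)), 0, tolerance = 1e-9)
})

test_that("refitting on fitted values reproduces the coefficients", {
  dates <- month_dates(1998:1999)
  set.seed(41)
  D <- trend_distmat(dates, 1, 0.02, c(0.3, 0.1, 0, -0.1, -0.1, -0.1, -0.1))
  D <- D + matrix(0, nrow(D), ncol(D))
  noisy <- D
  up <- upper.tri(noisy)
  noisy[up] <- noisy[up] + rnorm(sum(up), 0, 0.05)
  noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
  fit1 <- fit_seasonal_trend(noisy, dates)
  refit_D <- noisy
  refit_D[cbind(fit1$pairs$a, fit1$pairs$b)] <- predict(fit1)
  refit_D[cbind(fit1$pairs$b, fit1$pairs$a)] <- predict(fit1)
  fit2 <- fit_seasonal_trend(refit_D, dates)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-9)
  expect_lt(abs(sum(fit1$beta2)), 1e-10)
})

test_that("the trend slope is recovered within 3 SE under noise", {
  dates <- month_dates(1998:2000)
  beta2 <- c(0.2, 0.1, 0, -0.05, -0.1, -0.1, -0.05)
  D0 <- trend_distmat(dates, 1, 0.01, beta2)
  signal_sd <- sd(D0[upper.tri(D0)])
  sigma <- signal_sd / 2                     # R^2 around 0.8
  set.seed(51)
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    D <- D0
    up <- upper.tri(D)
    D[up] <- D[up] + rnorm(sum(up), 0, sigma)
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    fit <- fit_seasonal_trend(D, dates)
    if (abs(fit$beta1 - 0.01) <= 3 * fit$se$beta1) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("rank problems and thin data raise informative errors", {
  dates <- month_dates(1998)[1:3, ]          # 3 pairs only
  D <- trend_distmat(dates, 1, 0, rep(0, 7))
  expect_error(fit_seasonal_trend(D, dates), "at least 9")
  # single calendar lag: all maps from the same calendar month
  dates2 <- data.frame(year = 1998:2003, month = 1)
  D2 <- trend_distmat(dates2, 1, 0, rep(0, 7))
  expect_error(fit_seasonal_trend(D2, dates2), "missing lag")
})

test_that("slope ratios divide trend slopes with sign handling", {
  dates <- month_dates(1998:1999)
  mkfit <- function(b1) fit_seasonal_trend(trend_distmat(dates, 1, b1, rep(0, 7)), dates)
  fa <- mkfit(0.0085); fb <- mkfit(0.001)
  expect_equal(slope_ratio(fa, fa), 1, tolerance = 1e-10)
  expect_equal(slope_ratio(fa, fb), 8.5, tolerance = 1e-6)
  expect_warning(r <- slope_ratio(fa, mkfit(-0.001)), "negative")
  expect_equal(r, -8.5, tolerance = 1e-6)
})

test_that("reference distance series normalizes and locates seasonal peaks", {
  ax <- depth_axis(seq(0, 200, 10))
  # blob depth oscillating with a 12-month period: W2 to January peaks at
  # maximal displacement
  months <- 1:24
  fields <- lapply(months, function(m)
    triangle_profile(ax, 100 + 40 * sin(2 * pi * (m - 1) / 12), halfwidth = 30))
  dates <- data.frame(year = 1998 + (months - 1) %/% 12,
                      month = (months - 1) %% 12 + 1)
  ser <- reference_distance_series(fields, dates, reference = 1,
                                   metric = "wasserstein", normalize = TRUE)
  expect_equal(ser$distance[1], 0)
  expect_equal(min(ser$distance), 0)
  expect_equal(max(ser$distance), 1)
  peaks <- attr(ser, "peaks")
  expect_true(all(peaks$month == 4))         # sin peaks in April
})
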