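test_that("the chlorophyll maximum is the argmax depth with shallow tie-break", {
  ax <- depth_axis(c(50, 96, 150))
  p <- oceanmover:::new_probability_field(c(0.125, 0.625, 0.25),
                                          data.frame(depth = ax$depths),
                                          "depth", axis = ax)
  expect_equal(estimate_dcm(p), 96)
  # uniform: shallowest depth wins the tie
  u <- normalize_field(depth_profile(ax, c(1, 1, 1)))
  expect_equal(estimate_dcm(u), 50)
  expect_equal(estimate_dcm(point_profile(depth_axis(seq(0, 200, 5)), 140)), 140)
})

test_that("profile comparisons return the shift for translates and the RMSE formula", {
  ax <- depth_axis(seq(0, 200, 4))
  pa <- triangle_profile(ax, 96)
  expect_equal(unname(compare_profiles(pa, pa)), c(0, 0))

  pb <- shift_profile(pa, 44)
  cc <- compare_profiles(pa, pb)
  expect_equal(unname(cc["w2"]), 44, tolerance = 1e-10)

  # point masses at 96 and 140 on a shared axis
  q1 <- point_profile(ax, 96); q2 <- point_profile(ax, 140)
  cc2 <- compare_profiles(q1, q2)
  expect_equal(unname(cc2["w2"]), 44)
  expect_equal(unname(cc2["rmse"]), sqrt(2 / length(ax$depths)))

  # different axes: W2 fine, RMSE undefined
  pb2 <- triangle_profile(depth_axis(seq(0, 200, 5)), 96)
  expect_warning(cc3 <- compare_profiles(pa, pb2), "different depth axes")
  expect_true(is.na(cc3["rmse"]))
})

test_that("generated profiles hit their target peak and stay normalized", {
  ax <- depth_axis(seq(0, 200, 5))
  p <- make_profile(ax, dcm_depth = 96, noise = 0)
  expect_equal(estimate_dcm(p), 95)     # nearest axis depth to 96
  expect_lt(abs(sum(p$probs) - 1), 1e-12)
  expect_true(all(p$probs >= 0))
  # determinism of the seeded noise
  expect_identical(make_profile(ax, 96, noise = 0.02, seed = 9)$probs,
                   make_profile(ax, 96, noise = 0.02, seed = 9)$probs)
  expect_false(identical(make_profile(ax, 96, noise = 0.02, seed = 9)$probs,
                         make_profile(ax, 96, noise = 0.02, seed = 10)$probs))
  # generated profiles agree with the quantile oracle under transport
  pa <- make_profile(ax, 96, noise = 0); pb <- make_profile(ax, 140, noise = 0)
  expect_lt(abs(solve_transport(pa, pb)$w2 - wasserstein_1d(pa, pb)), 1e-8)
})

test_that("DCM regressions separate shift-tracking from saturating distances", {
  ax <- depth_axis(seq(0, 200, 5))
  base <- triangle_profile(ax, 50, halfwidth = 20)
  shifts <- seq(0, 120, 10)
  cmp <- do.call(rbind, lapply(shifts, function(s) {
    compare_profile_pair(base, shift_profile(base, s))
  }))
  fit <- dcm_regression(cmp)
  # pure shifts: W2 is exactly linear in the DCM difference
  expect_equal(fit$table["w2", "r.squared"], 1, tolerance = 1e-9)
  expect_equal(fit$table["w2", "slope"], 1, tolerance = 1e-9)
  # RMSE saturates once supports disjoin, so it tracks the shift worse
  expect_lt(fit$table["rmse", "r.squared"], fit$table["w2", "r.squared"])

  # duplicating the dataset leaves R^2 unchanged
  fit2 <- dcm_regression(rbind(cmp, cmp))
  expect_equal(fit2$table$r.squared, fit$table$r.squared, tolerance = 1e-12)

  # null: distances unrelated to the DCM difference have mean R^2 near zero
  set.seed(71)
  # under the null, E[R^2] = 1/(n-2), so n = 40 puts the mean near 0.026
  r2 <- replicate(200, {
    n <- 40
    fake <- data.frame(w2 = rnorm(n), rmse = rnorm(n),
                       dcm_diff = runif(n, 0, 100))
    dcm_regression(fake)$table["w2", "r.squared"]
  })
  expect_lt(mean(r2), 0.05)

  expect_error(dcm_regression(cmp[1:2, ]), "at least 3")
  cmp0 <- cmp; cmp0$dcm_diff <- 5
  expect_error(dcm_regression(cmp0), "constant")
})

test_that("pooled transport concentrates at the systematic peak mismatch", {
  ax <- depth_axis(seq(0, 200, 4))
  set.seed(81)
  plans <- lapply(1:10, function(k) {
    pa <- make_profile(ax, 96, width_m = 15, surface_level = 0.02,
                       noise = 0.003, seed = k)
    pb <- make_profile(ax, 140, width_m = 15, surface_level = 0.02,
                       noise = 0.003, seed = 100 + k)
    solve_transport(pa, pb)
  })
  pooled <- pool_transport_summaries(plans)
  # the heaviest pooled movement runs from near 96 m down to near 140 m
  expect_lt(abs(pooled$depth_i[1] - 96), 10)
  expect_lt(abs(pooled$depth_j[1] - 140), 10)
})
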