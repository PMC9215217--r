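test_that("small instances solve to their enumerable optima", {
  # point mass to point mass: the only feasible plan
  d <- matrix(250, 1, 1)
  pl <- solve_transport(1, 1, d)
  expect_equal(pl$w2, 250)
  expect_equal(pl$arcs$mass, 1)

  # two cells 100 km apart, P=(1,0), Q=(.5,.5): move half across
  d2 <- matrix(c(0, 100, 100, 0), 2)
  pl2 <- solve_transport(c(1, 0), c(0.5, 0.5), d2)
  expect_equal(pl2$objective, 5000)
  expect_equal(pl2$w2, 100 / sqrt(2))

  # P = Q: zero cost exactly
  p <- c(0.2, 0.3, 0.5)
  d3 <- matrix(runif(9, 10, 100), 3); diag(d3) <- 0
  expect_identical(solve_transport(p, p, d3)$w2, 0)
})

test_that("network simplex agrees with the dense LP oracle on random instances", {
  set.seed(101)
  for (k in 1:40) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    P <- rand_prob(m); Q <- rand_prob(n)
    d <- matrix(runif(m * n, 0, 50), m, n)
    pl <- solve_transport(P, Q, d)
    expect_lt(abs(pl$objective - solve_transport_lp_oracle(P, Q, d)), 1e-9)
    expect_lt(max_marginal_error(pl, P, Q), 1e-10)
    expect_lt(abs(pl$w2^2 - pl$objective), 1e-10)
    expect_true(all(pl$arcs$mass > 0))
  }
})

test_that("masked arcs are honoured and infeasibility is reported", {
  d <- matrix(c(0, 10, 10, 0), 2)
  dm <- mask_long_arcs(d, 5)
  # feasible only when marginals already match
  pl <- solve_transport(c(0.5, 0.5), c(0.5, 0.5), dm)
  expect_identical(pl$w2, 0)
  expect_error(solve_transport(c(1, 0), c(0.5, 0.5), dm), "no feasible",
               class = "omd_infeasible_error")
  # oracle agrees on a feasible masked instance
  set.seed(5)
  P <- rand_prob(6); Q <- rand_prob(6)
  co <- rand_geo_coords(6)
  dg <- mask_long_arcs(great_circle_matrix(co), 15000)
  expect_lt(abs(solve_transport(P, Q, dg)$objective -
                solve_transport_lp_oracle(P, Q, dg)), 1e-9)
})

test_that("unbalanced inputs are rejected, near-one sums are renormalized", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(solve_transport(c(0.7, 0.7), c(0.5, 0.5), d), "unbalanced")
  expect_message(pl <- solve_transport(c(0.5 + 5e-10, 0.5), c(0.5, 0.5), d,
                                       tol = 1e-8), "renormalizing")
  expect_lt(max_marginal_error(pl, c(0.5 + 5e-10, 0.5), c(0.5, 0.5)), 1e-10)
})

test_that("1D transport matches the quantile closed form", {
  ax <- depth_axis(seq(0, 200, 5))
  set.seed(202)
  for (k in 1:30) {
    pa <- rand_profile(ax); pb <- rand_profile(ax)
    expect_lt(abs(solve_transport(pa, pb)$w2 - wasserstein_1d(pa, pb)), 1e-8)
  }
  # pure translate: W2 equals the shift exactly (axis step dividing 44)
  ax <- depth_axis(seq(0, 200, 4))
  pa <- triangle_profile(ax, 96)
  pb <- shift_profile(pa, 44)
  expect_equal(solve_transport(pa, pb)$w2, 44, tolerance = 1e-12)
  expect_equal(wasserstein_1d(pa, pb), 44, tolerance = 1e-12)
  # point masses: single arc
  expect_equal(wasserstein_1d(point_profile(ax, 96), point_profile(ax, 140)), 44)
  expect_identical(wasserstein_1d(pa, pa), 0)
})

test_that("W2 satisfies the metric axioms on a common support", {
  set.seed(303)
  co <- rand_geo_coords(20)
  d <- great_circle_matrix(co)
  for (k in 1:30) {
    P <- rand_prob(20); Q <- rand_prob(20); R <- rand_prob(20)
    wpq <- solve_transport(P, Q, d)$w2
    wqp <- solve_transport(Q, P, t(d))$w2
    wqr <- solve_transport(Q, R, d)$w2
    wpr <- solve_transport(P, R, d)$w2
    expect_gte(wpq, 0)
    expect_lt(abs(wpq - wqp), 1e-10)
    expect_gte(wpq + wqr - wpr, -1e-8)
    expect_identical(solve_transport(P, P, d)$w2, 0)
  }
})

test_that("scaling all base distances scales W2 linearly", {
  set.seed(404)
  P <- rand_prob(8); Q <- rand_prob(8)
  d <- matrix(runif(64, 1, 40), 8)
  w1 <- solve_transport(P, Q, d)$w2
  for (s in c(0.5, 3.7, 1000)) {
    expect_equal(solve_transport(P, Q, s * d)$w2, s * w1, tolerance = 1e-12)
  }
})

test_that("top-mass arcs follow the cumulative rule with deterministic ties", {
  mkplan <- function(mass, dist = rep(1, length(mass))) {
    structure(list(arcs = data.frame(i = seq_along(mass), j = seq_along(mass),
                                     mass = mass, dist = dist),
                   objective = sum(mass * dist^2), w2 = sqrt(sum(mass * dist^2)),
                   source = NULL, target = NULL, units = "km"),
              class = "transport_plan")
  }
  tm <- top_mass_arcs(mkplan(c(0.5, 0.3, 0.15, 0.05)), 0.10)
  expect_equal(tm$top$mass, 0.5)
  expect_equal(nrow(tm$rest), 3L)

  # single arc is the top set for any fraction
  expect_equal(nrow(top_mass_arcs(mkplan(1), 0.99)$top), 1L)

  # ten equal arcs: exactly one, the smallest (i, j)
  tm10 <- top_mass_arcs(mkplan(rep(0.1, 10)), 0.10)
  expect_equal(nrow(tm10$top), 1L)
  expect_equal(tm10$top$i, 1L)

  # zero-cost plan: both sets empty
  tz <- top_mass_arcs(mkplan(c(0.6, 0.4), dist = c(0, 0)), 0.10)
  expect_equal(nrow(tz$top), 0L)
  expect_equal(nrow(tz$rest), 0L)
})

test_that("plan summaries expose endpoints and pool additively", {
  ax <- depth_axis(seq(0, 200, 4))
  pa <- point_profile(ax, 96); pb <- point_profile(ax, 140)
  pl <- solve_transport(pa, pb)
  ts <- transport_summary(pl)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$depth_i, 96)
  expect_equal(ts$depth_j, 140)
  expect_equal(ts$mass, 1)
  expect_equal(ts$dist, 44)

  # zero-cost plan -> empty table
  expect_equal(nrow(transport_summary(solve_transport(pa, pa))), 0L)

  # pooling two identical plans doubles the mass
  pooled <- pool_transport_summaries(list(pl, pl))
  expect_equal(pooled$mass, 2)
  expect_equal(pooled$depth_i, 96)
})
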