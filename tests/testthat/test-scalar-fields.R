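test_that("normalization divides by the total over valid cells", {
  g <- grid_spec(c(0, 1, 2), 0)
  f <- scalar_field(g, c(2, 3, 5))
  p <- normalize_field(f)
  expect_equal(p$probs, c(0.2, 0.3, 0.5))

  # constant field -> uniform
  fc <- scalar_field(g, c(4, 4, 4))
  expect_equal(normalize_field(fc)$probs, rep(1 / 3, 3))

  # masked cell excluded; observed zero stays in the support with prob 0
  g4 <- grid_spec(c(0, 1, 2, 3), 0, mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 1))
  p4 <- normalize_field(scalar_field(g4, c(1, 7, 1, 0)))
  expect_equal(p4$probs, c(0.5, 0.5, 0))
  expect_equal(p4$coords$lon, c(0, 2, 3))
})

test_that("normalization is scale invariant and sums to one on the valid support", {
  set.seed(7)
  for (k in 1:20) {
    g <- grid_spec(seq(-10, 10, 5), seq(0, 20, 5),
                   mask = matrix(runif(25) > 0.2, 5, 5))
    v <- rep(NA_real_, 25)
    v[oceanmover:::rowmajor(g$mask)] <- runif(sum(g$mask))
    f <- scalar_field(g, v)
    p1 <- normalize_field(f)
    c0 <- runif(1, 0.01, 100)
    p2 <- normalize_field(scalar_field(g, v * c0))
    expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
    expect_lt(abs(sum(p1$probs) - 1), 1e-12)
    expect_equal(p1$support, oceanmover:::field_support(f))
  }
})

test_that("degenerate fields are rejected", {
  g <- grid_spec(c(0, 1), 0)
  expect_error(normalize_field(scalar_field(g, c(0, 0))), "zero total mass")
  expect_error(scalar_field(g, c(-1, 2)), "negative")
  expect_error(grid_spec(c(200, 1), 0), "longitude")
  expect_error(depth_axis(c(10, 10)), "strictly increasing")
})

test_that("colocalization averages model values inside the window", {
  win <- colocalization_window()
  samples <- data.frame(date = 10, depth = 100, value = 0.5)
  model <- data.frame(date = c(9, 12), depth = c(98, 103), value = c(0.2, 0.4))
  out <- colocalize(model, samples, win)
  expect_equal(out$model, 0.3)   # both records inside +/-2 days, +/-5 m

  # exact match reproduces the record
  out2 <- colocalize(data.frame(date = 10, depth = 100, value = 0.7), samples, win)
  expect_equal(out2$model, 0.7)

  # outside the window: dropped and reported; all-dropped errors
  model_far <- data.frame(date = 14, depth = 100, value = 0.9)
  expect_error(colocalize(model_far, samples, win), "no overlapping records")
  two <- rbind(samples, data.frame(date = 14.5, depth = 100, value = 0.6))
  expect_message(out3 <- colocalize(model_far, two, win), "dropped")
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$insitu, 0.6)
  expect_equal(nrow(attr(out3, "dropped")), 1L)
})

test_that("colocalization window boundaries are inclusive", {
  win <- colocalization_window(2, 5)
  s <- data.frame(date = 10, depth = 100, value = 1)
  m <- data.frame(date = c(8, 12), depth = c(95, 105), value = c(1, 3))
  expect_equal(colocalize(m, s, win)$model, 2)
})

test_that("profiles built from samples bin to the nearest depth and normalize", {
  ax <- depth_axis(c(50, 96, 150))
  s <- data.frame(date = NA, depth = c(50, 96, 150), value = c(0.1, 0.5, 0.2))
  p <- profile_from_samples(s, ax)
  expect_equal(p$probs, c(0.125, 0.625, 0.25))

  # single depth -> point mass; two equal values -> half/half
  expect_equal(profile_from_samples(data.frame(depth = 96, value = 2),
                                    ax)$probs[2], 1)
  p2 <- profile_from_samples(data.frame(depth = c(50, 150), value = c(3, 3)), ax)
  expect_equal(p2$probs, c(0.5, 0, 0.5))

  # same-bin samples are averaged before normalization
  p3 <- profile_from_samples(data.frame(depth = c(49, 51, 150),
                                        value = c(1, 3, 2)), ax)
  expect_equal(p3$probs, c(0.5, 0, 0.5))

  expect_error(profile_from_samples(data.frame(depth = 10, value = NA), ax),
               "missing")
})
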