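test_that("normalisation pins the reference PD to 1 and is scale invariant", {
  s <- fluorescence_series("MitoSOX", c(27, 30, 35, 40), c(2, 3, 5, 9))
  n1 <- normalize_series(s, 27)
  expect_equal(n1$value[1], 1)
  expect_equal(normalize_series(n1, 27), n1)                  # idempotent
  s2 <- dplyr::mutate(s, value = value * 17.3)
  expect_equal(normalize_series(s2, 27)$value, n1$value)      # scale invariant
  ## interpolated reference works too
  n3 <- normalize_series(s, 28.5)
  expect_equal(approx(n3$pd, n3$value, xout = 28.5)$y, 1)
  expect_error(normalize_series(s, 20), "outside the PD range")
})

test_that("series interpolation is piecewise linear with no extrapolation", {
  s <- fluorescence_series("x", c(30, 32, 40), c(1, 3, 5))
  expect_equal(interpolate_series(s, c(30, 32, 40)), c(1, 3, 5))
  expect_equal(interpolate_series(s, 31), 2)
  expect_error(interpolate_series(s, 29), "not extrapolated")

  ## dense-resampling oracle: manual two-point linear formula
  set.seed(501)
  q <- runif(100, 30, 40)
  manual <- vapply(q, function(p) {
    i <- findInterval(p, s$pd, rightmost.closed = TRUE)
    w <- (p - s$pd[i]) / (s$pd[i + 1] - s$pd[i])
    (1 - w) * s$value[i] + w * s$value[i + 1]
  }, 0)
  expect_equal(interpolate_series(s, q), manual, tolerance = 1e-12)
})

test_that("the MSMM ratio divides separately normalised channels", {
  pd <- c(27, 30, 35, 40)
  mito <- fluorescence_series("MitoSOX", pd, c(2, 4, 8, 16))
  expect_equal(msmm_ratio(mito, mito, 27)$value, rep(1, 4)) # identical inputs

  mass_const <- fluorescence_series("mass", pd, rep(5, 4))
  r <- msmm_ratio(mito, mass_const, 27)
  expect_equal(r$value, normalize_series(mito, 27)$value)   # constant mass

  ## constructed inverse: mitosox = ratio_truth * mass pointwise
  ratio_truth <- c(1, 1.5, 2.5, 4)
  mass <- fluorescence_series("mass", pd, c(3, 3.3, 4.1, 5))
  mito2 <- fluorescence_series("MitoSOX", pd, ratio_truth * mass$value)
  r2 <- msmm_ratio(mito2, mass, 27)
  expect_equal(r2$value, ratio_truth / ratio_truth[1], tolerance = 1e-12)
  ## ratio grid is the union of knots in the overlap; invariant to rescaling
  mass_scaled <- dplyr::mutate(mass, value = value * 0.01)
  expect_equal(msmm_ratio(mito2, mass_scaled, 27)$value, r2$value)

  disjoint <- fluorescence_series("mass", c(50, 55), c(1, 2))
  expect_error(msmm_ratio(mito, disjoint, 27), "do not overlap")
})

test_that("model-observation comparison reports Pearson r and residuals", {
  pd <- 27:40
  pred <- fluorescence_series("MSMM", pd, 1 + 0.3 * (pd - 27))
  expect_equal(compare_model_to_observed(pred, pred)$r, 1)

  affine <- dplyr::mutate(pred, value = 2 * value + 1)
  expect_equal(compare_model_to_observed(pred, affine)$r, 1)

  few <- fluorescence_series("MSMM", c(27, 28), c(1, 2))
  expect_error(compare_model_to_observed(few, few), "at least 3")

  cmp <- compare_model_to_observed(pred, affine, at = "knots")
  expect_equal(glance(cmp)$at, "knots")
  expect_equal(nrow(tidy(cmp)), length(pd))
})

test_that("normalising and interpolating commute at any query PD", {
  s <- fluorescence_series("x", c(27, 31, 36, 44), c(2, 5, 7, 13))
  q <- c(28, 30.5, 36, 41.2)
  a <- interpolate_series(normalize_series(s, 27), q)
  b <- interpolate_series(s, q) / interpolate_series(s, 27)
  expect_equal(a, b, tolerance = 1e-12)
})
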