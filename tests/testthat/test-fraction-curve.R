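test_that("fraction curves validate, sort, and enforce monotone senescence", {
  c2 <- fraction_curve(data.frame(pd = c(25, 47), s_mean = c(0, 1),
                                  s_lower = c(0, 0.95), s_upper = c(0.05, 1)))
  expect_s3_class(c2, "fraction_curve")

  ## sort invariance
  tbl <- tibble::tibble(pd = c(40, 25, 47), s_mean = c(0.5, 0, 1),
                        s_lower = c(0.4, 0, 0.9), s_upper = c(0.6, 0.1, 1))
  expect_equal(fraction_curve(tbl)$pd, c(25, 40, 47))
  expect_equal(fraction_curve(tbl)$s_mean, c(0, 0.5, 1))

  bad <- tibble::tibble(pd = c(25, 30, 47), s_mean = c(0.5, 0.2, 1),
                        s_lower = c(0, 0, 0.9), s_upper = c(1, 1, 1))
  expect_error(fraction_curve(bad), "irreversible")
  repaired <- fraction_curve(bad, repair = TRUE)
  expect_false(is.unsorted(repaired$s_mean))

  expect_error(fraction_curve(tibble::tibble(
    pd = c(25, 47), s_mean = c(0, 1.2), s_lower = c(0, 1), s_upper = c(0, 1.3)
  )), "\\[0, 1\\]")
  expect_error(fraction_curve(tibble::tibble(
    pd = c(25, 47), s_mean = c(0.5, 1), s_lower = c(0.6, 1), s_upper = c(0.7, 1)
  )), "s_lower <= s_mean")
  expect_error(fraction_curve(tbl[1, ]), "at least 2")
})

test_that("interpolation is exact at knots, linear between, clamped outside", {
  curve <- fraction_curve(tibble::tibble(
    pd = c(30, 35, 40), s_mean = c(0.2, 0.4, 0.9),
    s_lower = c(0.1, 0.3, 0.8), s_upper = c(0.3, 0.5, 1.0)
  ))
  at_knots <- interpolate_fraction(curve, c(30, 35, 40))
  expect_equal(at_knots$s_mean, c(0.2, 0.4, 0.9))
  expect_equal(at_knots$s_lower, c(0.1, 0.3, 0.8))

  expect_equal(interpolate_fraction(curve, 32.5)$s_mean, 0.3)
  expect_equal(interpolate_fraction(curve, 20)$s_mean, 0.2)  # clamp low
  expect_equal(interpolate_fraction(curve, 99)$s_upper, 1.0) # clamp high

  ## piecewise linearity: second differences vanish within each segment
  fine <- interpolate_fraction(curve, seq(30, 35, by = 0.25))$s_mean
  expect_equal(max(abs(diff(diff(fine)))), 0, tolerance = 1e-12)
})

test_that("state sampling follows the fraction and is seed-reproducible", {
  all0 <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 0,
                                        s_lower = 0, s_upper = 0))
  all1 <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 1,
                                        s_lower = 1, s_upper = 1))
  set.seed(1)
  expect_true(all(sample_states(all0, 30, 500) == "proliferating"))
  expect_true(all(sample_states(all1, 30, 500) == "senescent"))

  half <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 0.5,
                                        s_lower = 0.499, s_upper = 0.501))
  set.seed(2)
  draws <- sample_states(half, 36, 1e5)
  expect_equal(mean(draws == "senescent"), 0.5, tolerance = 0.01) # +-0.005 abs

  set.seed(33); a <- sample_states(half, 36, 100)
  set.seed(33); b <- sample_states(half, 36, 100)
  expect_identical(a, b)

  ## mean mode is deterministic given the RNG stream of the bernoulli draws
  set.seed(4); m1 <- sample_states(half, 36, 1e4, mode = "mean")
  expect_equal(mean(m1 == "senescent"), 0.5, tolerance = 0.02)
})
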