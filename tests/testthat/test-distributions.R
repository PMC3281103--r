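test_that("gamma fitting recovers known parameters and matches sample moments", {
  set.seed(301)
  x <- rgamma(1e5, shape = 2, scale = 3)
  fit <- fit_gamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.02)
  expect_equal(fit$scale, 3, tolerance = 0.02)
  ## gamma MLE ties the fitted mean to the sample mean
  expect_equal(fit$shape * fit$scale, mean(x), tolerance = 0.001)
  expect_equal(sqrt(fit$shape) * fit$scale, sd(x), tolerance = 0.02)

  td <- tidy(fit)
  expect_equal(td$term, c("shape", "scale"))
  expect_true(all(td$std.error > 0))

  expect_error(fit_gamma(rep(2, 50)), "all equal")
  expect_error(fit_gamma(c(x[1:20], -1)), "positive")
  expect_error(fit_gamma(x[1:5]), "at least 10")
})

test_that("each distribution kind samples from the right law", {
  set.seed(302)
  ## degenerate empirical
  expect_equal(sample_phenotype(dist_empirical(3.5), 20), rep(3.5, 20))

  ## digitized uniform on [0, 1]: mean 1/2
  uni <- dist_digitized(c(0, 1), c(1, 1))
  u <- sample_phenotype(uni, 1e4)
  expect_lt(abs(mean(u) - 0.5), 3 * 0.289 / 100) # 3 se
  expect_true(all(u >= 0 & u <= 1))

  ## digitized triangular on [0, 1] with peak at 0: f(x) = 2(1 - x),
  ## analytic CDF 1 - (1 - x)^2
  tri <- dist_digitized(c(0, 1), c(2, 0))
  x <- sample_phenotype(tri, 1e4)
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - (1 - q)^2))
  expect_gt(ks$p.value, 0.01)

  ## gamma kind is parametric
  g <- sample_phenotype(dist_gamma(4, 0.25), 1e4)
  expect_equal(mean(g), 1, tolerance = 0.02)

  expect_error(dist_digitized(c(0, 1), c(-1, 2)), "non-negative")
  expect_error(dist_digitized(c(1, 0), c(1, 1)), "ascending")
  expect_error(dist_empirical(numeric(0)), "empty")
})

test_that("mixture simulation draws each cell from the right component", {
  set.seed(303)
  dP <- dist_gamma(4, 0.25); dS <- dist_gamma(2, 3.3)
  ## boundary fractions reduce to the pure components
  p0 <- simulate_mixture(dP, dS, 0, 1e4)
  expect_gt(suppressWarnings(stats::ks.test(p0, sample_phenotype(dP, 1e4)))$p.value, 0.01)
  p1 <- simulate_mixture(dP, dS, 1, 1e4)
  expect_gt(suppressWarnings(stats::ks.test(p1, sample_phenotype(dS, 1e4)))$p.value, 0.01)

  ## mixture mean matches the two-component expectation
  s <- 0.3
  mix <- simulate_mixture(dP, dS, s, 1e4)
  mu <- (1 - s) * dist_mean(dP) + s * dist_mean(dS)
  sdm <- sqrt(mixture_variance(
    state_moments(dist_mean(dP), dist_sd(dP)^2, dist_mean(dS), dist_sd(dS)^2), s
  ))
  expect_equal(mean(mix), mu, tolerance = 3 * sdm / sqrt(1e4) / mu)
})

test_that("exceedance fractions detect stochastic ordering", {
  expect_equal(exceedance_fraction(rep(1, 5), rep(1, 7)), 0) # strict inequality
  set.seed(304)
  a <- rnorm(5e3); b <- rnorm(5e3)
  expect_equal(exceedance_fraction(a, b), 0.5, tolerance = 3 * 0.012)
  expect_gt(exceedance_fraction(a + 1, a), 0.5)
  ## sampled mode estimates the same quantity
  expect_equal(exceedance_fraction(a, b, mode = "sampled"), 0.5, tolerance = 0.05)
  expect_error(exceedance_fraction(numeric(0), a), "non-empty")
})

test_that("intermediate-PD populations bootstrap the matching boundary sample", {
  set.seed(305)
  eP <- dist_empirical(rgamma(2000, 4, scale = 0.25))
  eS <- dist_empirical(rgamma(2000, 2, scale = 3.3))
  all0 <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 0,
                                        s_lower = 0, s_upper = 0))
  sim0 <- simulate_intermediate_population(eP, eS, all0, 30, 1e4)
  ## ECDF distance to the source sample stays small for a pure bootstrap
  d0 <- max(abs(ecdf(sim0)(eP$values) - ecdf(eP$values)(eP$values)))
  expect_lt(d0, 0.05)
  all1 <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 1,
                                        s_lower = 1, s_upper = 1))
  sim1 <- simulate_intermediate_population(eP, eS, all1, 30, 1e4)
  expect_lt(max(abs(ecdf(sim1)(eS$values) - ecdf(eS$values)(eS$values))), 0.05)

  ## self-consistency at s = 0.5 against an exact 50:50 mixture
  half <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 0.5,
                                        s_lower = 0.48, s_upper = 0.52))
  simh <- simulate_intermediate_population(eP, eS, half, 36, 1e4)
  ref <- c(sample_phenotype(eP, 5000), sample_phenotype(eS, 5000))
  expect_equal(exceedance_fraction(simh, ref), 0.5, tolerance = 0.03)
})
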