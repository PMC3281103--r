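test_that("mixture mean interpolates linearly between the two state means", {
  p <- phenotype_params(phi_P = 1, alpha = 5)
  expect_identical(mixture_mean(p, 0), 1)
  expect_identical(mixture_mean(p, 1), 5)
  expect_equal(mixture_mean(phenotype_params(2, 3), 0.5), 4)

  ## affine in s: finite-difference slope equals phi_P * (alpha - 1) everywhere
  set.seed(11)
  for (i in 1:20) {
    phi <- runif(1, 0.1, 10); a <- runif(1, 1, 12)
    pp <- phenotype_params(phi, a)
    s <- sort(runif(5))
    slopes <- diff(mixture_mean(pp, s)) / diff(s)
    expect_equal(slopes, rep(phi * (a - 1), 4), tolerance = 1e-10)
  }

  ## alpha = 1 is the constant-phenotype (immortalised) limit
  p1 <- phenotype_params(2.5, 1)
  expect_equal(mixture_mean(p1, seq(0, 1, 0.1)), rep(2.5, 11))
})

test_that("mixture mean rejects invalid parameters and fractions", {
  expect_error(phenotype_params(1, 0.5), "phi_S >= phi_P")
  expect_error(phenotype_params(-1, 2), "positive")
  p <- phenotype_params(1, 2)
  expect_error(mixture_mean(p, -0.1), "\\[0, 1\\]")
  expect_error(mixture_mean(p, 1.2), "\\[0, 1\\]")
})

test_that("calibration reproduces the fold-change from boundary populations", {
  expect_equal(calibrate_params(1, 1)$alpha, 1)
  expect_equal(calibrate_params(2, 8)$alpha, 4)
  expect_error(calibrate_params(1, 0.5), "phi_S_obs < phi_P_obs")
})

test_that("mixture variance matches its boundaries and a Monte-Carlo oracle", {
  m <- state_moments(mean_P = 1, var_P = 4, mean_S = 1, var_S = 9)
  expect_equal(mixture_variance(m, 0), 4)
  expect_equal(mixture_variance(m, 1), 9)
  m0 <- state_moments(1, 0, 1, 0)
  expect_equal(mixture_variance(m0, 0.5), 0)
  ## constant in s when the states are identical
  meq <- state_moments(2, 3, 2, 3)
  expect_equal(mixture_variance(meq, seq(0, 1, 0.25)), rep(3, 5))

  ## independent two-component simulation oracle
  set.seed(21)
  mm <- state_moments(mean_P = 1, var_P = 1, mean_S = 8, var_S = 64)
  n <- 1e6
  sen <- runif(n) < 0.5
  draws <- ifelse(sen, rnorm(n, 8, 8), rnorm(n, 1, 1))
  expect_equal(mixture_variance(mm, 0.5), var(draws), tolerance = 0.01)

  expect_error(state_moments(1, -1, 2, 1), "non-negative")
})

test_that("predicted trajectories are the mixture mean applied along s(PD)", {
  curve <- make_sigmoid_curve()
  params <- phenotype_params(1, 10)
  grid <- seq(25, 47, by = 0.5)
  traj <- predict_trajectory(params, curve, grid)
  s <- interpolate_fraction(curve, grid)$s_mean
  expect_identical(traj$value, mixture_mean(params, s)) # exact identity
  expect_false(is.unsorted(traj$value)) # non-decreasing for ascending s

  ## flat curve: flat series at phi_P
  flat <- fraction_curve(tibble::tibble(pd = c(25, 47), s_mean = 0,
                                        s_lower = 0, s_upper = 0))
  expect_equal(predict_trajectory(params, flat, grid)$value, rep(1, length(grid)))

  ## step curve: series steps phi_P -> alpha * phi_P
  stepc <- fraction_curve(tibble::tibble(pd = c(30, 30.001), s_mean = c(0, 1),
                                         s_lower = c(0, 1), s_upper = c(0, 1)))
  v <- predict_trajectory(params, stepc, c(25, 29, 31, 40))$value
  expect_equal(v, c(1, 1, 10, 10))

  expect_error(predict_trajectory(params, curve, numeric(0)), "empty")
})
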