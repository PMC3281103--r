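test_that("study bundles are byte-identical under a fixed seed", {
  cfg <- study_config(seed = 77, n_cells_per_pd = 100L)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  m1 <- generate_study(cfg, d1)
  m2 <- generate_study(cfg, d2)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(file.exists(file.path(d1, m1$files))))
})

test_that("study configuration enforces mixture/per-cell consistency", {
  expect_error(study_config(alpha = 5), "alpha \\* phi_P")
  expect_error(study_config(phi_P = 2), "phi_P")
  cfg <- study_config()
  expect_gt(cfg$sd_ratio, 8)   # senescent heterogeneity regime
  expect_lt(cfg$mean_ratio, 7)
  ht <- study_config(hTERT = TRUE)
  expect_equal(ht$alpha, 1)
})

test_that("noiseless bundles reproduce the closed-form prediction exactly", {
  cfg <- study_config(seed = 5, noise_sd = 0, n_cells_per_pd = 100L)
  d <- file.path(tempdir(), "bundle_noiseless")
  generate_study(cfg, d)
  series <- read_series(file.path(d, "series.csv"))
  curve <- read_fraction_curve(file.path(d, "fraction_curve.csv"))
  mito <- dplyr::filter(series, channel == "MitoSOX")
  params <- calibrate_params(mito$value[1], mito$value[nrow(mito)])
  pred <- predict_trajectory(params, curve, mito$pd)
  cmp <- compare_model_to_observed(
    fluorescence_series("p", pred$pd, pred$value), mito
  )
  expect_equal(cmp$r, 1, tolerance = 1e-9)
})

test_that("boundary per-cell files hold the pure state distributions", {
  cfg <- study_config(seed = 19, n_cells_per_pd = 2000L)
  d <- file.path(tempdir(), "bundle_cells")
  generate_study(cfg, d)
  first <- readr::read_csv(file.path(d, "cells_25.csv"), show_col_types = FALSE)
  last <- readr::read_csv(file.path(d, "cells_47.csv"), show_col_types = FALSE)
  expect_equal(mean(first$value), 1, tolerance = 0.05)        # gamma_P mean
  expect_equal(mean(last$value), 6.6, tolerance = 0.15)       # gamma_S mean
  expect_gt(sd(last$value) / sd(first$value), 5)              # far broader
})

test_that("hTERT bundles show flat kinetics with no senescent fold-change", {
  cfg <- study_config(seed = 23, hTERT = TRUE, n_cells_per_pd = 100L)
  d <- file.path(tempdir(), "bundle_htert")
  generate_study(cfg, d)
  series <- read_series(file.path(d, "series.csv"))
  mito <- dplyr::filter(series, channel == "MitoSOX")
  ## regression slope of mean fluorescence on PD is indistinguishable from 0
  fit <- summary(lm(value ~ pd, data = mito))
  expect_gt(fit$coefficients["pd", "Pr(>|t|)"], 0.05)
  curve <- read_fraction_curve(file.path(d, "fraction_curve.csv"))
  expect_true(all(curve$s_mean == 0))
})

test_that("volume-like digitized densities integrate to one and order correctly", {
  vd <- generate_volume_densities()
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(vd$proliferating$value, vd$proliferating$density), 1,
               tolerance = 1e-6)
  expect_equal(trap(vd$senescent$value, vd$senescent$density), 1,
               tolerance = 1e-6)
  dP <- dist_digitized(vd$proliferating$value, vd$proliferating$density)
  dS <- dist_digitized(vd$senescent$value, vd$senescent$density)
  expect_gt(dist_mean(dS), dist_mean(dP))
  expect_gt(dist_sd(dS), dist_sd(dP))
})

test_that("calibration and gamma fits recover the generator parameters", {
  cfg <- study_config(seed = 31, n_cells_per_pd = 5000L)
  d <- file.path(tempdir(), "bundle_recover")
  generate_study(cfg, d)
  vP <- readr::read_csv(file.path(d, "cells_25.csv"), show_col_types = FALSE)$value
  vS <- readr::read_csv(file.path(d, "cells_47.csv"), show_col_types = FALSE)$value
  cal <- calibrate_params(mean(vP), mean(vS))
  expect_equal(cal$alpha, cfg$alpha, tolerance = 0.05)
  expect_equal(fit_gamma(vP)$shape, cfg$gamma_P[["shape"]], tolerance = 0.08)
  expect_equal(fit_gamma(vS)$shape, cfg$gamma_S[["shape"]], tolerance = 0.08)
})
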