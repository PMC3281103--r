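#' Configuration for a synthetic senescence study
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the statistical structure the analysis assumes for an MRC5-fibroblast-like
#' culture aged from PD 25 to PD 47:
#'
#' * per-cell phenotype gamma distributions whose senescent member is far
#'   broader than the proliferating one (default sd ratio 9.33, above the
#'   reported 8-fold heterogeneity increase) while the mean fold-change
#'   `alpha` stays below 7 (default 6.6);
#' * a sigmoidal senescent-fraction curve rising from about 0 at the first
#'   PD to about 1 at the last, with a 95% confidence band;
#' * multiplicative log-normal measurement noise on population means
#'   (fluorescence means are positive, so noise acts on the log scale);
#' * an optional hTERT-immortalised regime in which no cell ever
#'   transitions (`alpha` forced to 1, flat kinetics).
#'
#' The construction enforces consistency between the mixture parameters and
#' the per-cell distributions: `mean(gamma_P) = phi_P` and
#' `mean(gamma_S) = alpha * phi_P`.
#'
#' @param seed Integer master seed for the whole bundle.
#' @param pd_range Length-2 ascending PD range (default `c(25, 47)`).
#' @param phi_P Proliferating mean phenotype (default 1, i.e. normalised).
#' @param alpha Senescent fold-change (default 6.6).
#' @param gamma_P,gamma_S Named vectors `c(shape =, scale =)` for the
#'   per-cell distributions. Defaults `(4, 0.25)` and `(2, 3.3)`.
#' @param curve_midpoint,curve_steepness Sigmoid parameters of `s(PD)`
#'   (defaults: midpoint 36, steepness 0.45 per PD).
#' @param band_width Scale of the confidence band: the standard error of
#'   `s` is `band_width * sqrt(s (1 - s))` (default 0.05).
#' @param noise_sd Relative (log-scale) sd of the multiplicative
#'   measurement noise on population means (default 0.05).
#' @param n_cells_per_pd Cells per per-cell snapshot file (default 500).
#' @param mass_alpha Fold-change of the mitochondrial-mass channel
#'   (senescent cells carry more mitochondria; default 2).
#' @param hTERT If `TRUE`, generate an immortalised control series:
#'   `alpha = 1`, identical state distributions, `s(PD)` identically 0.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         pd_range = c(25, 47),
                         phi_P = 1,
                         alpha = 6.6,
                         gamma_P = c(shape = 4, scale = 0.25),
                         gamma_S = c(shape = 2, scale = 3.3),
                         curve_midpoint = 36,
                         curve_steepness = 0.45,
                         band_width = 0.05,
                         noise_sd = 0.05,
                         n_cells_per_pd = 500L,
                         mass_alpha = 2,
                         hTERT = FALSE) {
  stopifnot(length(pd_range) == 2L, pd_range[1] < pd_range[2])
  if (isTRUE(hTERT)) {
    alpha <- 1
    gamma_S <- gamma_P
  }
  mean_P <- gamma_P[["shape"]] * gamma_P[["scale"]]
  mean_S <- gamma_S[["shape"]] * gamma_S[["scale"]]
  if (abs(mean_P - phi_P) > 1e-8 * max(phi_P, 1)) {
    abort("Inconsistent config: mean(gamma_P) must equal phi_P.")
  }
  if (abs(mean_S - alpha * phi_P) > 1e-6 * max(alpha * phi_P, 1)) {
    abort("Inconsistent config: mean(gamma_S) must equal alpha * phi_P.")
  }
  params <- phenotype_params(phi_P, alpha)
  structure(
    list(
      seed = as.integer(seed), pd_range = as.numeric(pd_range),
      phi_P = phi_P, alpha = alpha,
      gamma_P = gamma_P, gamma_S = gamma_S,
      curve_midpoint = curve_midpoint, curve_steepness = curve_steepness,
      band_width = band_width, noise_sd = noise_sd,
      n_cells_per_pd = as.integer(n_cells_per_pd),
      mass_alpha = mass_alpha, hTERT = isTRUE(hTERT),
      sd_ratio = (sqrt(gamma_S[["shape"]]) * gamma_S[["scale"]]) /
        (sqrt(gamma_P[["shape"]]) * gamma_P[["scale"]]),
      mean_ratio = mean_S / mean_P,
      params = params
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  PD range: ", x$pd_range[1], "-", x$pd_range[2],
      if (x$hTERT) "  [hTERT-immortalised]", "\n", sep = "")
  cat("  phi_P = ", x$phi_P, ", alpha = ", x$alpha,
      " (per-cell sd ratio ", format(x$sd_ratio, digits = 3), ")\n", sep = "")
  invisible(x)
}

## sigmoidal senescent-fraction curve implied by a config
config_curve_table <- function(config) {
  pd <- seq(config$pd_range[1], config$pd_range[2], by = 1)
  if (config$hTERT) {
    s <- rep(0, length(pd))
    se <- rep(0, length(pd))
  } else {
    s <- stats::plogis(config$curve_steepness * (pd - config$curve_midpoint))
    ## pin the study ends to the boundary states
    s <- (s - s[1]) / (s[length(s)] - s[1])
    se <- config$band_width * sqrt(s * (1 - s))
  }
  tibble(
    pd = pd,
    s_mean = s,
    s_lower = pmax(0, s - 1.96 * se),
    s_upper = pmin(1, s + 1.96 * se)
  )
}

#' Generate a complete synthetic study bundle
#'
#' Writes, under `dir`:
#'
#' * `fraction_curve.csv` — the sigmoidal `s(PD)` with confidence band;
#' * `series.csv` — per-PD population-mean MitoSOX and mitochondrial-mass
#'   fluorescence: the closed-form mixture prediction for each channel
#'   times multiplicative log-normal noise;
#' * `cells_<pd>.csv` — per-cell phenotype snapshots at the first PD (pure
#'   proliferating draws), the last PD (pure senescent draws), and three
#'   intermediate PDs (mixtures at the curve's mean fraction);
#' * `microscopy.csv` — per-cell marker records (`cell_id, pd, mitosox,
#'   ki67_positive, foci_count`) in which Ki67-negative cells with more
#'   than 5 foci carry the senescent phenotype distribution;
#' * `manifest.json` — config, seed, file list and MD5 content hashes.
#'
#' The same seed always produces a byte-identical bundle.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
generate_study <- function(config, dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  curve_tbl <- config_curve_table(config)
  curve <- fraction_curve(curve_tbl)
  readr::write_csv(curve_tbl, file.path(dir, "fraction_curve.csv"))

  ## population-mean series: mixture mean per channel, multiplicative noise.
  ## MitoSOX rises with both the phenotype and the mass fold-change; the
  ## mass channel with its own (milder) fold-change.
  pd <- curve_tbl$pd
  s <- curve_tbl$s_mean
  alpha_mito <- config$alpha * config$mass_alpha
  truth_mito <- config$phi_P * (1 + (alpha_mito - 1) * s)
  truth_mass <- 1 + (config$mass_alpha - 1) * s
  noise <- function(k) {
    if (config$noise_sd <= 0) rep(1, k) else rlnorm(k, 0, config$noise_sd)
  }
  series <- dplyr::bind_rows(
    tibble(channel = "MitoSOX", pd = pd, value = truth_mito * noise(length(pd))),
    tibble(channel = "mito_mass", pd = pd, value = truth_mass * noise(length(pd)))
  )
  readr::write_csv(series, file.path(dir, "series.csv"))

  ## per-cell snapshots: boundary PDs are pure states; intermediates mix
  dP <- dist_gamma(config$gamma_P[["shape"]], config$gamma_P[["scale"]])
  dS <- dist_gamma(config$gamma_S[["shape"]], config$gamma_S[["scale"]])
  cell_pds <- unique(round(quantile(pd, c(0, 0.25, 0.5, 0.75, 1))))
  cells_files <- character(0)
  for (p in cell_pds) {
    sp <- interpolate_fraction(curve, p)$s_mean
    if (p == min(pd)) sp <- 0
    if (p == max(pd)) sp <- if (config$hTERT) 0 else 1
    vals <- simulate_mixture(dP, dS, sp, config$n_cells_per_pd)
    f <- file.path(dir, paste0("cells_", p, ".csv"))
    readr::write_csv(
      tibble(cell_id = seq_along(vals), channel = "MitoSOX", value = vals), f
    )
    cells_files <- c(cells_files, basename(f))
  }

  ## microscopy marker table at three PDs, ~50 cells per condition
  micro_pds <- unique(round(quantile(pd, c(0.1, 0.5, 0.9))))
  micro <- purrr::map_dfr(micro_pds, function(p) {
    n <- 50L
    sp <- interpolate_fraction(curve, p)$s_mean
    senescent <- runif(n) < sp
    ki67 <- ifelse(senescent, FALSE, runif(n) < 0.85)
    foci <- integer(n)
    foci[senescent] <- 6L + rpois(sum(senescent), 3)
    foci[!senescent] <- pmin(rpois(sum(!senescent), 1.2), 5L)
    high <- !ki67 & foci > 5L
    mito <- numeric(n)
    if (any(high)) mito[high] <- sample_phenotype(dS, sum(high))
    if (any(!high)) mito[!high] <- sample_phenotype(dP, sum(!high))
    tibble(cell_id = seq_len(n), pd = p, mitosox = mito,
           ki67_positive = as.integer(ki67), foci_count = foci)
  })
  readr::write_csv(micro, file.path(dir, "microscopy.csv"))

  files <- c("fraction_curve.csv", "series.csv", cells_files, "microscopy.csv")
  manifest <- list(
    generator = "senstep::generate_study",
    seed = config$seed,
    config = config[c("pd_range", "phi_P", "alpha", "gamma_P", "gamma_S",
                      "curve_midpoint", "curve_steepness", "band_width",
                      "noise_sd", "n_cells_per_pd", "mass_alpha", "hTERT")],
    files = files,
    md5 = as.list(setNames(
      unname(tools::md5sum(file.path(dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a pair of volume-like digitized densities
#'
#' Emulates digitized cell-volume probability-density tables for a
#' proliferating and a senescent population: two skewed unimodal densities
#' on a shared positive 100-point grid, the senescent one broader and
#' right-shifted, each renormalised to unit area by the trapezoid rule.
#'
#' @param grid_max Upper end of the value grid (default 12).
#' @param n_grid Number of grid points (default 100).
#' @return A list with tibbles `proliferating` and `senescent`, each with
#'   columns `value`, `density`.
#' @export
generate_volume_densities <- function(grid_max = 12, n_grid = 100L) {
  grid <- seq(0, grid_max, length.out = n_grid)
  dP <- dgamma(grid, shape = 8, scale = 0.25)   # mean 2, sd 0.71
  dS <- dgamma(grid, shape = 3, scale = 1.3)    # mean 3.9, sd 2.25
  norm <- function(d) d / trapezoid_area(grid, d)
  list(
    proliferating = tibble(value = grid, density = norm(dP)),
    senescent = tibble(value = grid, density = norm(dS))
  )
}
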