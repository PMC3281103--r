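#' Run the full step-model analysis pipeline
#'
#' Executes the end-to-end analysis on a study bundle (a directory with
#' `series.csv` and `fraction_curve.csv`, optionally `cells_<pd>.csv` and
#' `microscopy.csv`, as written by [generate_study()]):
#'
#' 1. read and validate the inputs;
#' 2. normalise each fluorescence channel at the reference PD and build
#'    the MitoSOX/mass ratio (MSMM);
#' 3. calibrate `phi_P` and `alpha` from the series values at the
#'    proliferating and senescent reference PDs;
#' 4. predict each channel's trajectory from the senescent-fraction curve
#'    and compare it with the observation (Pearson r, residuals);
#' 5. when per-cell files are present: fit gamma distributions to the
#'    boundary snapshots, dip-test a 50:50 step-model mixture for
#'    unimodality, and simulate intermediate-PD populations for an
#'    exceedance comparison against the observed snapshots;
#' 6. when `microscopy.csv` is present: classify cells by Ki67 and foci
#'    count and summarise MitoSOX by group;
#' 7. write `report.json` (and trajectory/density plots unless disabled)
#'    into `out_dir`.
#'
#' A calibrated fold-change below `htert_tol` is flagged as an
#' "hTERT-like regime": flat kinetics indistinguishable from an
#' immortalised culture.
#'
#' @param input A bundle directory, or a [study_config()] (the bundle is
#'   then generated under `out_dir/study`).
#' @param out_dir Output directory for `report.json` and plots.
#' @param ref_pd Normalisation reference PD; default: earliest PD common
#'   to both channels.
#' @param calib_pds Length-2 PDs of the proliferating and senescent
#'   calibration populations; default: ends of the common PD range.
#' @param dip_n Mixture sample size for the unimodality test (default 500,
#'   a practically observable population size).
#' @param dip_boot Bootstrap replicates for the dip test (default 2000).
#' @param n_intermediate Cells per intermediate-PD simulation (default 10000).
#' @param seed Seed for all stochastic stages.
#' @param htert_tol Fold-change threshold for the hTERT-like flag
#'   (default 1.2, about two standard errors of the calibration ratio under
#'   5% multiplicative measurement noise).
#' @param write_plots Write trajectory/density plots as PDFs (default TRUE).
#' @return Invisibly, the report as a list (also written as JSON).
#' @export
run_pipeline <- function(input, out_dir,
                         ref_pd = NULL, calib_pds = NULL,
                         dip_n = 500L, dip_boot = 2000L,
                         n_intermediate = 10000L,
                         seed = 1L, htert_tol = 1.2,
                         write_plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(input, "study_config")) {
    bundle_dir <- file.path(out_dir, "study")
    generate_study(input, bundle_dir)
  } else {
    bundle_dir <- input
  }
  need <- c("series.csv", "fraction_curve.csv")
  missing_files <- need[!file.exists(file.path(bundle_dir, need))]
  if (length(missing_files) > 0) {
    abort(paste0("Missing required input files in '", bundle_dir, "': ",
                 paste(missing_files, collapse = ", ")))
  }
  set.seed(as.integer(seed))

  series <- read_series(file.path(bundle_dir, "series.csv"))
  curve <- read_fraction_curve(file.path(bundle_dir, "fraction_curve.csv"))
  chans <- unique(series$channel)
  if (length(chans) < 2L) {
    abort("series.csv must contain at least two channels (MitoSOX and mass).")
  }
  mito_chan <- if ("MitoSOX" %in% chans) "MitoSOX" else chans[1]
  mass_chan <- if ("mito_mass" %in% chans) "mito_mass" else setdiff(chans, mito_chan)[1]
  mito <- dplyr::filter(series, .data$channel == mito_chan)
  mass <- dplyr::filter(series, .data$channel == mass_chan)

  lo <- max(min(mito$pd), min(mass$pd))
  hi <- min(max(mito$pd), max(mass$pd))
  if (is.null(ref_pd)) ref_pd <- lo
  if (is.null(calib_pds)) calib_pds <- c(lo, hi)

  msmm <- msmm_ratio(mito, mass, ref_pd)
  channels <- list(MitoSOX = normalize_series(mito, ref_pd),
                   mito_mass = normalize_series(mass, ref_pd),
                   MSMM = msmm)

  comparisons <- purrr::imap(channels, function(obs, name) {
    phi_P_obs <- interpolate_series(obs, calib_pds[1])
    phi_S_obs <- interpolate_series(obs, calib_pds[2])
    ## a noisy flat series can put the senescent reference slightly below the
    ## proliferating one; the model's ordering assumption then clamps the
    ## fold-change to its boundary (alpha = 1, flat regime)
    params <- if (phi_S_obs < phi_P_obs) {
      phenotype_params(phi_P_obs, 1)
    } else {
      calibrate_params(phi_P_obs, phi_S_obs)
    }
    pred <- predict_trajectory(params, curve, obs$pd, channel = name)
    cmp <- compare_model_to_observed(
      fluorescence_series(name, pred$pd, pred$value), obs
    )
    list(params = params, predicted = pred, comparison = cmp)
  })

  alpha_msmm <- comparisons$MSMM$params$alpha
  report <- list(
    package = "senstep",
    version = as.character(utils::packageVersion("senstep")),
    seed = as.integer(seed),
    input = normalizePath(bundle_dir),
    ref_pd = ref_pd,
    calibration_pds = calib_pds,
    parameters = purrr::map(comparisons, function(x)
      list(phi_P = x$params$phi_P, alpha = x$params$alpha)),
    pearson_r = purrr::map(comparisons, function(x) x$comparison$r),
    htert_like = alpha_msmm < htert_tol,
    regime = if (alpha_msmm < htert_tol) {
      "hTERT-like regime: flat phenotype kinetics, no senescent fold-change"
    } else "senescing culture"
  )

  ## optional per-cell distribution analyses
  cell_files <- sort(list.files(bundle_dir, pattern = "^cells_[0-9.]+\\.csv$"))
  if (length(cell_files) >= 2L) {
    cell_pds <- as.numeric(sub("^cells_([0-9.]+)\\.csv$", "\\1", cell_files))
    ord <- order(cell_pds)
    cell_files <- cell_files[ord]; cell_pds <- cell_pds[ord]
    read_cells <- function(f) {
      readr::read_csv(file.path(bundle_dir, f), show_col_types = FALSE)$value
    }
    vals_P <- read_cells(cell_files[1])
    vals_S <- read_cells(cell_files[length(cell_files)])
    fit_P <- fit_gamma(vals_P)
    fit_S <- fit_gamma(vals_S)
    mix <- simulate_mixture(as_dist(fit_P), as_dist(fit_S), 0.5, dip_n)
    dip <- dip_test(mix, n_boot = dip_boot)
    report$gamma_fits <- list(
      proliferating = list(shape = fit_P$shape, scale = fit_P$scale, n = fit_P$n),
      senescent = list(shape = fit_S$shape, scale = fit_S$scale, n = fit_S$n)
    )
    report$dip <- list(statistic = dip$statistic, p_value = dip$p_value,
                       n = dip$n, n_boot = dip$n_boot,
                       unimodal_at_0.05 = dip$p_value > 0.05)

    mid <- cell_files[-c(1, length(cell_files))]
    mid_pds <- cell_pds[-c(1, length(cell_pds))]
    if (length(mid) > 0) {
      eP <- dist_empirical(vals_P); eS <- dist_empirical(vals_S)
      report$exceedance <- purrr::map2(mid, mid_pds, function(f, p) {
        obs <- read_cells(f)
        sim <- simulate_intermediate_population(eP, eS, curve, p, n_intermediate)
        list(pd = p, fraction = exceedance_fraction(sim, obs),
             n_simulated = length(sim), n_observed = length(obs))
      })
    }
  }

  micro_path <- file.path(bundle_dir, "microscopy.csv")
  if (file.exists(micro_path)) {
    micro <- readr::read_csv(micro_path, show_col_types = FALSE)
    gs <- group_summary(classify_cells(micro))
    report$markers <- list(
      summary = as.list(gs$summary),
      high_foci_flag = gs$high_foci_flag,
      alpha = gs$alpha
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(write_plots)) {
    obs_all <- dplyr::bind_rows(channels)
    pred_all <- purrr::imap_dfr(comparisons, function(x, name)
      dplyr::mutate(x$predicted, channel = name))
    p1 <- plot_trajectories(obs_all, pred_all)
    ggplot2::ggsave(file.path(out_dir, "trajectories.pdf"), p1,
                    width = 7, height = 4.5)
    p2 <- autoplot(curve)
    ggplot2::ggsave(file.path(out_dir, "fraction_curve.pdf"), p2,
                    width = 6, height = 4)
  }
  invisible(report)
}
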