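# senstep

Population-mean mitochondrial ROS production rises smoothly — roughly
exponentially — as primary fibroblast cultures (e.g. MRC5) are passaged
towards replicative senescence. `senstep` implements and tests a simple
explanation that needs no gradual per-cell damage accumulation: a
**stochastic step model**, in which each cell's phenotype is drawn from a
narrow *proliferating* distribution until, at a random population doubling
(PD), it steps once and irreversibly to a draw from a broader, higher
*senescent* distribution. Population kinetics are then a two-component
mixture with a changing weight:

```
phi_Mix(s) = p * phi_P + s * phi_S
           = phi_P * (1 + (alpha - 1) * s),    p + s = 1,  phi_S = alpha * phi_P
```

where `s(PD)` is the senescent fraction (estimated upstream from growth
curves) and `alpha >= 1` the senescent fold-change. The package is for
researchers analysing flow-cytometry or microscopy time courses of ageing
cultures who want to ask: *are my population kinetics and per-cell
distributions consistent with discrete state switching?*

It provides, as tidyverse-style functions over data frames:

* the closed-form mixture mean/variance and calibration from boundary
  populations (`mixture_mean()`, `mixture_variance()`, `calibrate_params()`,
  `predict_trajectory()`);
* senescent-fraction curves with confidence bands, linear interpolation and
  uncertainty-propagating state sampling (`fraction_curve()`,
  `interpolate_fraction()`, `sample_states()`);
* a per-cell step simulator with strictly non-decreasing transitions
  (`simulate_cells()`, `cell_trace()`, `population_summary()`);
* distribution machinery: gamma ML fits, empirical and digitized-density
  samplers, mixture simulation, a from-scratch Hartigan dip test of
  unimodality, and Mann–Whitney exceedance comparisons (`fit_gamma()`,
  `dip_test()`, `exceedance_fraction()`, ...);
* fluorescence time-course normalisation, MitoSOX/mitochondrial-mass ratio
  construction and model validation (`normalize_series()`, `msmm_ratio()`,
  `compare_model_to_observed()`);
* Ki67 / γH2A.X-foci marker classification and group comparison
  (`classify_cells()`, `group_summary()`);
* a seeded synthetic-study generator and an end-to-end pipeline
  (`study_config()`, `generate_study()`, `run_pipeline()`).

Results objects support `tidy()`/`glance()` and `autoplot()`.

## Worked example

Generate a synthetic ageing study (PD 25–47, senescent fold-change 6.6, 5%
measurement noise) and run the full analysis:

```r
library(senstep)

p <- phenotype_params(phi_P = 1, alpha = 6.6)
mixture_mean(p, c(0, 0.25, 0.5, 1))
#> [1] 1.0 2.4 3.8 6.6

cfg <- study_config(seed = 42)
rep <- run_pipeline(cfg, "analysis_out", seed = 42)

unlist(rep$pearson_r)
#>   MitoSOX mito_mass      MSMM
#> 0.9930839 0.9822853 0.9678337
rep$parameters$MSMM$alpha
#> [1] 6.353582
rep$dip$p_value
#> [1] 0.9935032
sapply(rep$exceedance, function(e) e$fraction)
#> [1] 0.4991166 0.4778426 0.4947018
rep$markers$high_foci_flag
#> [1] TRUE
```

Reading these numbers: the model calibrated only from the youngest and
oldest populations tracks the intermediate observations closely (Pearson
r ≈ 0.97–0.99 per channel); the recovered fold-change (≈ 6.4) sits near the
generator's truth (6.6) given two noisy calibration points; a 50:50
proliferating/senescent mixture of 500 cells is *not* flagged as bimodal by
the dip test (p ≈ 0.99) even though the senescent component's standard
deviation is 9-fold larger — the step model predicts unimodal-looking
mixtures in this regime; simulated intermediate populations exceed observed
ones about 50% of the time (no systematic shift); and the Ki67-negative,
>5-foci cells have significantly higher MitoSOX than both other marker
groups. `run_pipeline()` also writes `report.json` and plots into the
output directory.

See `vignettes/step-model.Rmd` for the model's assumptions, parameter
choices and design decisions.

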