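#' Phenotype parameters of the two-state mixture model
#'
#' The step model describes a cell population as a mixture of two discrete
#' states: proliferation-competent cells with expected phenotype `phi_P`
#' (e.g. MitoSOX/mitochondrial-mass ratio in arbitrary fluorescence units)
#' and replicatively senescent cells with expected phenotype
#' `phi_S = alpha * phi_P`. `alpha` is the dimensionless senescent
#' fold-change and must be at least 1: the senescent phenotype is assumed
#' never to fall below the proliferating one. `alpha = 1` is the
#' constant-phenotype limit seen in hTERT-immortalised cultures.
#'
#' @param phi_P Mean proliferating phenotype, arbitrary units, `> 0`.
#' @param alpha Senescent/proliferating fold-change, `>= 1`.
#'
#' @return An object of class `phenotype_params`.
#' @seealso [calibrate_params()], [mixture_mean()], [predict_trajectory()]
#' @export
#' @examples
#' phenotype_params(phi_P = 1, alpha = 6.6)
phenotype_params <- function(phi_P, alpha) {
  if (!is.numeric(phi_P) || length(phi_P) != 1L || !is.finite(phi_P) || phi_P <= 0) {
    abort("`phi_P` must be a single positive number.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    abort("`alpha` must be a single finite number.")
  }
  if (alpha < 1) {
    abort(paste0(
      "`alpha` = ", format(alpha), " < 1 violates the model's ordering ",
      "assumption phi_S >= phi_P; the senescent phenotype must not be ",
      "smaller than the proliferating one."
    ))
  }
  structure(list(phi_P = phi_P, alpha = alpha), class = "phenotype_params")
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("Step-model phenotype parameters\n")
  cat("  phi_P (proliferating mean): ", format(x$phi_P), "\n", sep = "")
  cat("  alpha (senescent fold-change): ", format(x$alpha), "\n", sep = "")
  cat("  phi_S = alpha * phi_P: ", format(x$phi_P * x$alpha), "\n", sep = "")
  invisible(x)
}

#' Calibrate mixture parameters from boundary populations
#'
#' Estimates `phi_P` as the mean phenotype of a population known to be
#' essentially fully proliferating (in practice a culture at low population
#' doubling, PD < 30) and `alpha` as the ratio of the mean phenotype of a
#' fully senescent population (near the Hayflick limit) to `phi_P`.
#'
#' @param phi_P_obs Observed mean phenotype of the proliferating reference
#'   population (`> 0`).
#' @param phi_S_obs Observed mean phenotype of the senescent reference
#'   population; must be at least `phi_P_obs`.
#'
#' @return A [phenotype_params()] object with `alpha = phi_S_obs / phi_P_obs`.
#' @export
#' @examples
#' calibrate_params(2, 8) # alpha = 4
calibrate_params <- function(phi_P_obs, phi_S_obs) {
  if (!is.numeric(phi_P_obs) || length(phi_P_obs) != 1L || phi_P_obs <= 0 ||
      !is.numeric(phi_S_obs) || length(phi_S_obs) != 1L || phi_S_obs <= 0) {
    abort("`phi_P_obs` and `phi_S_obs` must be single positive numbers.")
  }
  if (phi_S_obs < phi_P_obs) {
    abort(paste0(
      "phi_S_obs < phi_P_obs: the model assumes the senescent phenotype ",
      "exceeds the proliferating one (phi_S >= phi_P), so the senescent ",
      "reference mean cannot be smaller than the proliferating reference mean."
    ))
  }
  phenotype_params(phi_P = phi_P_obs, alpha = phi_S_obs / phi_P_obs)
}

#' Expected phenotype of a mixed population
#'
#' For a senescent fraction `s` (and proliferating fraction `p = 1 - s`) the
#' population mean phenotype is
#' `phi_Mix = p * phi_P + s * phi_S = phi_P * (1 + (alpha - 1) * s)`,
#' the substitution of `phi_S = alpha * phi_P` and `p = 1 - s` into the
#' two-component mixture mean. It is affine and non-decreasing in `s`,
#' equals `phi_P` at `s = 0` and `alpha * phi_P` at `s = 1`.
#'
#' @param params A [phenotype_params()] object.
#' @param s Senescent fraction(s) in `[0, 1]`; vectorised.
#'
#' @return Numeric vector of mixture mean phenotypes, same length as `s`.
#' @export
#' @examples
#' p <- phenotype_params(1, 5)
#' mixture_mean(p, c(0, 0.5, 1)) # 1, 3, 5
mixture_mean <- function(params, s) {
  stopifnot(inherits(params, "phenotype_params"))
  check_fraction(s, "s")
  params$phi_P * (1 + (params$alpha - 1) * s)
}

#' Per-state phenotype moments
#'
#' Container for the mean and variance of the proliferating and senescent
#' per-cell phenotype distributions, used by [mixture_variance()].
#'
#' @param mean_P,mean_S State means (`> 0`).
#' @param var_P,var_S State variances (`>= 0`).
#' @return An object of class `state_moments`.
#' @export
state_moments <- function(mean_P, var_P, mean_S, var_S) {
  vals <- c(mean_P = mean_P, var_P = var_P, mean_S = mean_S, var_S = var_S)
  if (!all(is.finite(vals))) abort("All moments must be finite numbers.")
  if (mean_P <= 0 || mean_S <= 0) abort("State means must be positive.")
  if (var_P < 0 || var_S < 0) abort("State variances must be non-negative.")
  structure(as.list(vals), class = "state_moments")
}

#' Variance of the mixed-population phenotype
#'
#' Variance of the two-component mixture under the assumption that the two
#' state distributions are independent (zero covariance between them):
#' `Var = (1 - s) * var_P + s * var_S + s * (1 - s) * (mean_S - mean_P)^2`.
#' The within-state terms are the averaged state variances; the last term is
#' the between-state spread. At `s = 0` it reduces to `var_P`, at `s = 1`
#' to `var_S`.
#'
#' @param moments A [state_moments()] object.
#' @param s Senescent fraction(s) in `[0, 1]`; vectorised.
#' @return Numeric vector of mixture variances.
#' @export
#' @examples
#' m <- state_moments(mean_P = 1, var_P = 1, mean_S = 8, var_S = 64)
#' mixture_variance(m, 0.5)
mixture_variance <- function(moments, s) {
  stopifnot(inherits(moments, "state_moments"))
  check_fraction(s, "s")
  (1 - s) * moments$var_P + s * moments$var_S +
    s * (1 - s) * (moments$mean_S - moments$mean_P)^2
}

#' Predict the population phenotype trajectory over population doublings
#'
#' Combines the senescent-fraction curve `s(PD)` with the mixture mean:
#' at every queried PD the expected phenotype is
#' `mixture_mean(params, s(PD))`. Queries outside the curve's knot range are
#' clamped to the end values (the fraction curve is never extrapolated).
#'
#' @param params A [phenotype_params()] object.
#' @param curve A [fraction_curve()] object.
#' @param pd_grid Numeric vector of population doubling values (non-empty).
#' @param channel Channel label attached to the output series.
#'
#' @return A fluorescence-series tibble with columns `channel`, `pd`,
#'   `value`, plus the interpolated `s` used at each PD.
#' @export
predict_trajectory <- function(params, curve, pd_grid, channel = "predicted") {
  stopifnot(inherits(params, "phenotype_params"))
  if (length(pd_grid) == 0L) abort("`pd_grid` must not be empty.")
  if (anyNA(pd_grid) || !is.numeric(pd_grid)) abort("`pd_grid` must be numeric without NA.")
  s <- interpolate_fraction(curve, pd_grid)$s_mean
  tibble(
    channel = channel,
    pd = as.numeric(pd_grid),
    s = s,
    value = mixture_mean(params, s)
  )
}

## shared argument check: fractions live in [0, 1]
check_fraction <- function(s, name) {
  if (!is.numeric(s) || anyNA(s)) abort(paste0("`", name, "` must be numeric without NA."))
  if (any(s < 0 | s > 1)) {
    abort(paste0("`", name, "` must lie in [0, 1]; got values outside that range."))
  }
  invisible(s)
}
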