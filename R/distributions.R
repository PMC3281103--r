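#' Per-cell phenotype distributions
#'
#' A `phenotype_dist` describes the per-cell phenotype (fluorescence, volume,
#' ...) of one cell state. Three kinds are supported:
#'
#' * `dist_gamma(shape, scale)` — parametric gamma, the family fitted to
#'   microscopically observed per-cell MitoSOX levels;
#' * `dist_empirical(values)` — an observed sample, resampled with
#'   replacement;
#' * `dist_digitized(value, density)` — a digitized probability-density
#'   table (e.g. read off a published figure), interpolated linearly between
#'   grid points, renormalised by the trapezoid rule and sampled by
#'   inverse-CDF.
#'
#' Support must be non-negative in all cases: fluorescence intensities and
#' cell volumes are non-negative quantities.
#'
#' @param shape,scale Gamma parameters, both `> 0`.
#' @param values Numeric vector of observed per-cell values, all `>= 0`.
#' @param value,density Digitized density table: ascending values and
#'   non-negative densities with positive total mass.
#'
#' @return An object of class `phenotype_dist`.
#' @name phenotype_dist
NULL

#' @rdname phenotype_dist
#' @export
dist_gamma <- function(shape, scale) {
  if (!is.numeric(shape) || !is.numeric(scale) || length(shape) != 1L ||
      length(scale) != 1L || shape <= 0 || scale <= 0) {
    abort("`shape` and `scale` must be single positive numbers.")
  }
  structure(list(kind = "gamma", shape = shape, scale = scale),
            class = "phenotype_dist")
}

#' @rdname phenotype_dist
#' @export
dist_empirical <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) abort("`values` must not be empty.")
  if (anyNA(values) || any(values < 0)) {
    abort("Empirical phenotype values must be non-negative and free of NA.")
  }
  structure(list(kind = "empirical", values = values), class = "phenotype_dist")
}

#' @rdname phenotype_dist
#' @export
dist_digitized <- function(value, density) {
  if (length(value) != length(density) || length(value) < 2L) {
    abort("`value` and `density` must have equal length >= 2.")
  }
  if (anyNA(value) || anyNA(density)) abort("Digitized table must not contain NA.")
  if (is.unsorted(value, strictly = TRUE)) abort("`value` must be strictly ascending.")
  if (any(value < 0)) abort("Digitized support must be non-negative.")
  if (any(density < 0)) abort("Densities must be non-negative.")
  area <- trapezoid_area(value, density)
  if (area <= 0) abort("Digitized density must have positive total mass.")
  structure(list(kind = "digitized", value = as.numeric(value),
                 density = as.numeric(density) / area),
            class = "phenotype_dist")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.phenotype_dist <- function(x, ...) {
  switch(x$kind,
    gamma = cat("Phenotype distribution: gamma(shape = ", format(x$shape),
                ", scale = ", format(x$scale), ")\n", sep = ""),
    empirical = cat("Phenotype distribution: empirical sample of ",
                    length(x$values), " values\n", sep = ""),
    digitized = cat("Phenotype distribution: digitized density on ",
                    length(x$value), " grid points\n", sep = "")
  )
  invisible(x)
}

#' Mean and standard deviation of a phenotype distribution
#'
#' Exact for the gamma kind; sample moments for the empirical kind;
#' trapezoid-rule moments of the interpolated density for the digitized kind.
#'
#' @param dist A [phenotype_dist] object.
#' @return A single number.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "phenotype_dist"))
  switch(dist$kind,
    gamma = dist$shape * dist$scale,
    empirical = mean(dist$values),
    digitized = trapezoid_area(dist$value, dist$value * dist$density)
  )
}

#' @rdname dist_mean
#' @export
dist_sd <- function(dist) {
  stopifnot(inherits(dist, "phenotype_dist"))
  switch(dist$kind,
    gamma = sqrt(dist$shape) * dist$scale,
    empirical = stats::sd(dist$values),
    digitized = {
      m <- dist_mean(dist)
      sqrt(max(trapezoid_area(dist$value, (dist$value - m)^2 * dist$density), 0))
    }
  )
}

#' Sample per-cell phenotypes from a distribution
#'
#' Gamma kind samples parametrically; empirical kind samples the observed
#' values with replacement; digitized kind samples by inverse-CDF on the
#' piecewise-linear (trapezoid-normalised) density.
#'
#' Uses the global R random stream; call `set.seed()` for reproducibility.
#'
#' @param dist A [phenotype_dist] object.
#' @param n Number of draws (`>= 1`).
#' @return Numeric vector of length `n`.
#' @export
sample_phenotype <- function(dist, n) {
  stopifnot(inherits(dist, "phenotype_dist"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  switch(dist$kind,
    gamma = rgamma(n, shape = dist$shape, scale = dist$scale),
    empirical = dist$values[sample.int(length(dist$values), n, replace = TRUE)],
    digitized = sample_digitized(dist, n)
  )
}

## Inverse-CDF sampling of a piecewise-linear density (already normalised to
## unit area at construction). On each grid segment the CDF is quadratic;
## invert segment-wise: solve f0*t + slope*t^2/2 = m for the mass m to be
## accumulated inside the segment.
sample_digitized <- function(dist, n) {
  x <- dist$value; f <- dist$density
  seg_area <- diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2
  cdf <- c(0, cumsum(seg_area))
  u <- runif(n) * cdf[length(cdf)] # guard tiny normalisation drift
  seg <- findInterval(u, cdf, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > length(seg_area)] <- length(seg_area)
  x0 <- x[seg]; w <- x[seg + 1L] - x0
  f0 <- f[seg]; f1 <- f[seg + 1L]
  m <- u - cdf[seg]
  slope <- (f1 - f0) / w
  out <- numeric(n)
  lin <- abs(f1 - f0) <= 1e-12 * pmax(f0, f1)
  if (any(lin)) out[lin] <- x0[lin] + m[lin] / pmax(f0[lin], 1e-300)
  i <- !lin
  if (any(i)) {
    a <- slope[i] / 2; b <- f0[i]; cc <- -m[i]
    disc <- pmax(b^2 - 4 * a * cc, 0)
    t <- (-b + sqrt(disc)) / (2 * a)
    out[i] <- x0[i] + pmin(pmax(t, 0), w[i])
  }
  out
}

#' Fit a gamma distribution to per-cell phenotype values
#'
#' Maximum-likelihood gamma fit (via \pkg{fitdistrplus}). The gamma family
#' is used for per-cell fluorescence because intensities are positive and
#' right-skewed. At the MLE the fitted mean `shape * scale` matches the
#' sample mean (exactly, up to optimiser tolerance).
#'
#' @param values At least 10 strictly positive, not all equal, values.
#' @return An object of class `gamma_fit` with elements `shape`, `scale`,
#'   `loglik`, `n` and the underlying `fitdistrplus` fit. Supports
#'   [tidy()] and [glance()].
#' @export
fit_gamma <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L) abort("Need at least 10 values to fit a gamma.")
  if (anyNA(values) || any(values <= 0)) {
    abort("Gamma fitting requires strictly positive values without NA.")
  }
  if (stats::sd(values) == 0) abort("Values are all equal; gamma fit is degenerate.")
  fit <- fitdistrplus::fitdist(values, "gamma", method = "mle",
                               keepdata = FALSE)
  est <- coef(fit)
  structure(
    list(shape = unname(est["shape"]), scale = 1 / unname(est["rate"]),
         loglik = fit$loglik, n = length(values),
         se = unname(fit$sd), fit = fit),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("Gamma fit (MLE, n = ", x$n, "): shape = ", format(x$shape),
      ", scale = ", format(x$scale),
      "; mean = ", format(x$shape * x$scale), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    std.error = c(x$se[1], x$se[2] / (1 / x$scale)^2) # delta method for scale
  )
}

#' @export
glance.gamma_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n,
         mean = x$shape * x$scale, sd = sqrt(x$shape) * x$scale)
}

#' Convert a gamma fit to a phenotype distribution
#' @param x A `gamma_fit` object.
#' @return A [dist_gamma()] distribution.
#' @export
as_dist <- function(x) {
  stopifnot(inherits(x, "gamma_fit"))
  dist_gamma(shape = x$shape, scale = x$scale)
}

#' Simulate a two-component mixture sample
#'
#' Each of the `n` cells is senescent with probability `s` (drawing its
#' phenotype from `dist_S`), otherwise proliferating (drawing from
#' `dist_P`). This is the population snapshot implied by the step model at
#' a fixed senescent fraction.
#'
#' @param dist_P,dist_S [phenotype_dist] objects for the proliferating and
#'   senescent states.
#' @param s Senescent fraction in `[0, 1]`.
#' @param n Number of cells.
#' @return Numeric vector of `n` per-cell phenotypes.
#' @export
simulate_mixture <- function(dist_P, dist_S, s, n) {
  stopifnot(inherits(dist_P, "phenotype_dist"), inherits(dist_S, "phenotype_dist"))
  check_fraction(s, "s")
  stopifnot(length(s) == 1L, n >= 1)
  n <- as.integer(n)
  senescent <- runif(n) < s
  out <- numeric(n)
  if (any(senescent)) out[senescent] <- sample_phenotype(dist_S, sum(senescent))
  if (any(!senescent)) out[!senescent] <- sample_phenotype(dist_P, sum(!senescent))
  out
}

#' Simulate an intermediate-PD population from boundary distributions
#'
#' Emulates the probabilistic mixture simulation used to predict phenotype
#' distributions at intermediate PDs: each of `n` cells is classified
#' proliferating or senescent by [sample_states()] (which propagates the
#' uncertainty in `s(PD)`), then draws its phenotype with replacement from
#' the matching boundary distribution.
#'
#' @param dist_P,dist_S [phenotype_dist] objects (typically empirical
#'   samples from a wholly proliferating and a wholly senescent PD).
#' @param curve A [fraction_curve()] object.
#' @param pd The PD at which to simulate.
#' @param n Number of cells (10,000 is a typical choice).
#' @param mode Passed to [sample_states()].
#' @return Numeric vector of `n` per-cell phenotypes.
#' @export
simulate_intermediate_population <- function(dist_P, dist_S, curve, pd, n,
                                             mode = c("uncertainty", "mean")) {
  stopifnot(inherits(dist_P, "phenotype_dist"), inherits(dist_S, "phenotype_dist"))
  mode <- match.arg(mode)
  state <- sample_states(curve, pd, n, mode = mode)
  senescent <- state == "senescent"
  out <- numeric(length(state))
  if (any(senescent)) out[senescent] <- sample_phenotype(dist_S, sum(senescent))
  if (any(!senescent)) out[!senescent] <- sample_phenotype(dist_P, sum(!senescent))
  out
}

#' Exceedance fraction between simulated and observed samples
#'
#' Estimates the probability that a simulated phenotype exceeds an observed
#' one. In `mode = "pairwise"` (default, deterministic) every
#' simulated/observed pair is compared and the proportion with
#' `simulated > observed` returned — the Mann-Whitney exceedance
#' probability estimator. In `mode = "sampled"` one observed value is drawn
#' uniformly with replacement for each simulated value, mirroring a
#' per-simulated-cell comparison; this is an unbiased randomised estimate
#' of the same quantity.
#'
#' A value near 0.5 indicates the simulated distribution neither
#' systematically exceeds nor falls below the observed one.
#'
#' @param simulated,observed Non-empty numeric vectors.
#' @param mode `"pairwise"` or `"sampled"`.
#' @return A fraction in `[0, 1]`.
#' @export
exceedance_fraction <- function(simulated, observed,
                                mode = c("pairwise", "sampled")) {
  mode <- match.arg(mode)
  if (length(simulated) == 0L || length(observed) == 0L) {
    abort("`simulated` and `observed` must be non-empty.")
  }
  if (mode == "sampled") {
    obs <- observed[sample.int(length(observed), length(simulated), replace = TRUE)]
    return(mean(simulated > obs))
  }
  ## pairwise via rank trick: count pairs simulated > observed
  r <- rank(c(simulated, observed), ties.method = "average")
  ns <- length(simulated); no <- length(observed)
  wins <- sum(r[seq_len(ns)]) - ns * (ns + 1) / 2 # Mann-Whitney U (ties = half)
  ties_half <- ties_correction(simulated, observed)
  (wins - ties_half) / (ns * no)
}

## number of tied cross pairs / 2 (rank-based U counts ties as half wins;
## strict inequality requires removing them)
ties_correction <- function(a, b) {
  common <- intersect(unique(a), unique(b))
  if (length(common) == 0L) return(0)
  sum(vapply(common, function(v) sum(a == v) * sum(b == v), 0)) / 2
}
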