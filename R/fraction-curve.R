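#' Senescent-fraction curve s(PD)
#'
#' Represents the fraction of senescent cells as a function of population
#' doubling (PD) as a piecewise-linear interpolation between knots, with a
#' 95% confidence band. Such curves are typically estimated upstream from
#' culture growth curves; here they are consumed as a table of knots.
#'
#' Invariants enforced: strictly ascending distinct PDs;
#' `0 <= s_lower <= s_mean <= s_upper <= 1` at every knot; `s_mean`
#' non-decreasing in PD (senescence is irreversible). A decreasing `s_mean`
#' is an error unless `repair = TRUE`, in which case an isotonic (pool
#' adjacent violators) projection replaces it.
#'
#' @param data A data frame with columns `pd`, `s_mean`, `s_lower`,
#'   `s_upper` (at least two rows). Rows may be in any order.
#' @param repair If `TRUE`, repair a non-monotone `s_mean` by isotonic
#'   regression instead of erroring. Default `FALSE`.
#'
#' @return A tibble with class `fraction_curve`.
#' @seealso [interpolate_fraction()], [sample_states()]
#' @export
#' @examples
#' fraction_curve(data.frame(
#'   pd = c(25, 47), s_mean = c(0, 1), s_lower = c(0, 0.95), s_upper = c(0.05, 1)
#' ))
fraction_curve <- function(data, repair = FALSE) {
  need <- c("pd", "s_mean", "s_lower", "s_upper")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", "), "."))
  }
  data <- as_tibble(data)[need]
  if (nrow(data) < 2L) abort("A fraction curve needs at least 2 knots.")
  if (anyNA(data)) abort("Fraction-curve knots must not contain NA.")
  if (anyDuplicated(data$pd)) abort("Knot PDs must be distinct.")
  data <- dplyr::arrange(data, .data$pd)

  for (col in c("s_mean", "s_lower", "s_upper")) {
    if (any(data[[col]] < 0 | data[[col]] > 1)) {
      abort(paste0("`", col, "` must lie in [0, 1] at every knot."))
    }
  }
  if (any(data$s_lower > data$s_mean) || any(data$s_mean > data$s_upper)) {
    abort("Need s_lower <= s_mean <= s_upper at every knot.")
  }
  if (is.unsorted(data$s_mean)) {
    if (!repair) {
      abort(paste0(
        "`s_mean` decreases between knots; senescence is irreversible so ",
        "s(PD) must be non-decreasing. Use `repair = TRUE` for an isotonic fit."
      ))
    }
    data$s_mean <- isotonic_fit(data$s_mean)
    data$s_lower <- pmin(data$s_lower, data$s_mean)
    data$s_upper <- pmax(data$s_upper, data$s_mean)
  }
  class(data) <- c("fraction_curve", class(data))
  data
}

#' Read a senescent-fraction curve from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `pd,s_mean,s_lower,s_upper` and `.` as decimal mark.
#'
#' @param path Path to the CSV file.
#' @inheritParams fraction_curve
#' @return A [fraction_curve()] object.
#' @export
read_fraction_curve <- function(path, repair = FALSE) {
  fraction_curve(readr::read_csv(path, show_col_types = FALSE), repair = repair)
}

## pool-adjacent-violators with equal weights
isotonic_fit <- function(y) {
  fit <- stats::isoreg(seq_along(y), y)
  fit$yf
}

#' Interpolate a fraction curve at arbitrary PDs
#'
#' Piecewise-linear interpolation of `s_mean`, `s_lower` and `s_upper`
#' independently between the bracketing knots; exact at knots. Queries
#' outside the knot range clamp to the end-knot values: `s` is a fraction
#' estimated only between the first and last observed PD and is not
#' extrapolated.
#'
#' @param curve A [fraction_curve()] object.
#' @param pd Numeric vector of query PDs.
#' @return A tibble with columns `pd`, `s_mean`, `s_lower`, `s_upper`.
#' @export
interpolate_fraction <- function(curve, pd) {
  stopifnot(inherits(curve, "fraction_curve"))
  if (!is.numeric(pd) || anyNA(pd)) abort("`pd` must be numeric without NA.")
  interp <- function(col) {
    approx(curve$pd, curve[[col]], xout = pd, rule = 2, ties = "ordered")$y
  }
  tibble(
    pd = as.numeric(pd),
    s_mean = interp("s_mean"),
    s_lower = interp("s_lower"),
    s_upper = interp("s_upper")
  )
}

#' Draw proliferating/senescent state labels at a given PD
#'
#' Each draw first samples a senescent probability `s*` from the uncertainty
#' distribution of the curve at `pd`, then assigns state `"senescent"` with
#' probability `s*` (else `"proliferating"`). The uncertainty distribution
#' is a Beta moment-matched to the interpolated mean and to
#' `(s_upper - s_lower) / (2 * 1.96)` as its standard deviation (the band is
#' read as a 95% confidence range); it degenerates to a point mass when the
#' band has zero width or the mean sits on a boundary. With
#' `mode = "mean"` the uncertainty is ignored and `s* = s_mean` always,
#' giving a deterministic mixing weight.
#'
#' Over many draws the senescent proportion converges to the mean of the
#' uncertainty distribution, which equals the interpolated `s_mean`.
#'
#' @param curve A [fraction_curve()] object.
#' @param pd A single PD at which to sample.
#' @param n Number of state labels to draw.
#' @param mode `"uncertainty"` (default) or `"mean"`.
#' @return Character vector of length `n` with values `"proliferating"` /
#'   `"senescent"`.
#' @export
sample_states <- function(curve, pd, n, mode = c("uncertainty", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(pd) == 1L, n >= 1L)
  at <- interpolate_fraction(curve, pd)
  s_star <- if (mode == "mean") {
    rep(at$s_mean, n)
  } else {
    rbeta_moment(n, mean = at$s_mean, sd = (at$s_upper - at$s_lower) / (2 * 1.96))
  }
  ifelse(runif(n) < s_star, "senescent", "proliferating")
}

## Beta draws moment-matched to (mean, sd); degenerate at boundaries or sd ~ 0.
## sd is capped just below the Bernoulli bound sqrt(m(1-m)) so the
## moment-matching always yields positive shapes.
rbeta_moment <- function(n, mean, sd) {
  if (sd <= 1e-12 || mean <= 0 || mean >= 1) return(rep(pmin(pmax(mean, 0), 1), n))
  sd <- min(sd, 0.99 * sqrt(mean * (1 - mean)))
  nu <- mean * (1 - mean) / sd^2 - 1
  rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @export
print.fraction_curve <- function(x, ...) {
  cat("Senescent-fraction curve: ", nrow(x), " knots over PD [",
      format(min(x$pd)), ", ", format(max(x$pd)), "]\n", sep = "")
  NextMethod()
}
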