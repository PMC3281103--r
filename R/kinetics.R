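#' Fluorescence time-course series
#'
#' A fluorescence series is a tibble with columns `channel` (label such as
#' `"MitoSOX"`, `"mito_mass"` or `"MSMM"`), `pd` and `value`, holding one
#' population-mean observation per PD for one or more channels. Within each
#' channel the PDs must be strictly ascending and the values positive.
#'
#' @param channel Channel label (recycled).
#' @param pd Numeric vector of population doublings.
#' @param value Positive fluorescence values.
#' @return A validated series tibble.
#' @export
fluorescence_series <- function(channel, pd, value) {
  out <- tibble(channel = channel, pd = as.numeric(pd), value = as.numeric(value))
  validate_series(out)
}

#' Read a multi-channel fluorescence series from CSV
#'
#' Expects header `channel,pd,value`, UTF-8, `.` decimal mark.
#' @param path Path to the CSV file.
#' @return A validated series tibble.
#' @export
read_series <- function(path) {
  validate_series(readr::read_csv(path, show_col_types = FALSE))
}

validate_series <- function(series, min_points = 2L) {
  need <- c("channel", "pd", "value")
  if (!all(need %in% names(series))) {
    abort("A fluorescence series needs columns: channel, pd, value.")
  }
  series <- as_tibble(series)[need]
  if (anyNA(series)) abort("Series must not contain NA.")
  if (any(series$value <= 0)) abort("Series values must be positive.")
  split_ok <- series |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n = dplyr::n(),
      ascending = !is.unsorted(.data$pd, strictly = TRUE)
    )
  if (any(split_ok$n < min_points)) {
    abort(paste0("Every channel needs at least ", min_points, " points."))
  }
  if (!all(split_ok$ascending)) {
    abort("PDs must be strictly ascending within each channel (sort first).")
  }
  series
}

one_channel <- function(series, what = "series") {
  if (length(unique(series$channel)) != 1L) {
    abort(paste0("Expected a single-channel ", what,
                 "; filter or split by `channel` first."))
  }
  series
}

#' Normalise a series to its value at a reference PD
#'
#' Divides every value by the (linearly interpolated) value at `ref_pd`,
#' per channel, so the series equals exactly 1 there. Normalising makes
#' time courses measured in different arbitrary-unit scales comparable;
#' it is idempotent and invariant to positive rescaling of the input.
#'
#' @param series A series tibble (one or more channels).
#' @param ref_pd Reference PD; must lie within every channel's PD range.
#' @return The normalised series tibble.
#' @export
normalize_series <- function(series, ref_pd) {
  series <- validate_series(series)
  series |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(df, key) {
      if (ref_pd < min(df$pd) || ref_pd > max(df$pd)) {
        abort(paste0("`ref_pd` = ", format(ref_pd), " is outside the PD range of ",
                     "channel '", key$channel, "'."))
      }
      ref <- approx(df$pd, df$value, xout = ref_pd)$y
      dplyr::mutate(df, value = .data$value / ref)
    }) |>
    dplyr::ungroup()
}

#' Linearly interpolate a single-channel series
#'
#' Piecewise-linear interpolation between observations; exact at knots.
#' No extrapolation: querying outside the observed PD range is an error.
#'
#' @param series A single-channel series tibble.
#' @param pd Numeric vector of query PDs within the series range.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_series <- function(series, pd) {
  series <- one_channel(validate_series(series))
  if (any(pd < min(series$pd)) || any(pd > max(series$pd))) {
    abort("Query PD outside the observed range; the series is not extrapolated.")
  }
  approx(series$pd, series$value, xout = pd)$y
}

#' MitoSOX / mitochondrial-mass ratio series (MSMM)
#'
#' Normalises the MitoSOX and mitochondrial-mass series separately at
#' `ref_pd` and returns their pointwise ratio on the union of both knot
#' grids restricted to the overlapping PD range (interpolating each series
#' linearly where it has no knot). The ratio is exactly 1 at `ref_pd` and
#' is invariant to independent positive rescaling of either input.
#'
#' @param mitosox,mass Single-channel series tibbles with overlapping PD
#'   ranges.
#' @param ref_pd Reference PD inside the overlap.
#' @param channel Output channel label.
#' @return A single-channel series tibble for the ratio.
#' @export
msmm_ratio <- function(mitosox, mass, ref_pd, channel = "MSMM") {
  mitosox <- one_channel(validate_series(mitosox), "mitosox")
  mass <- one_channel(validate_series(mass), "mass")
  lo <- max(min(mitosox$pd), min(mass$pd))
  hi <- min(max(mitosox$pd), max(mass$pd))
  if (lo >= hi) abort("The PD ranges of the two series do not overlap.")
  if (ref_pd < lo || ref_pd > hi) abort("`ref_pd` must lie in the PD overlap.")
  grid <- sort(unique(c(mitosox$pd, mass$pd)))
  grid <- grid[grid >= lo & grid <= hi]
  ms <- normalize_series(mitosox, ref_pd)
  mm <- normalize_series(mass, ref_pd)
  fluorescence_series(
    channel = channel,
    pd = grid,
    value = interpolate_series(ms, grid) / interpolate_series(mm, grid)
  )
}

#' Compare a predicted series with an observed one
#'
#' Evaluates both series on a common PD grid inside the overlap of their
#' ranges and reports the Pearson correlation between them, plus per-PD
#' residuals (observed minus predicted). With `at = "grid"` (default) the
#' common grid is the union of both knot sets; with `at = "knots"` only the
#' observed series' own PDs are used.
#'
#' @param predicted,observed Single-channel series tibbles.
#' @param at `"grid"` (union of knots) or `"knots"` (observed PDs only).
#' @return An object of class `series_comparison` with the correlation `r`
#'   (`NA` when either series is constant, e.g. a flat hTERT-like
#'   prediction), the comparison tibble, and the grid mode. Supports
#'   [tidy()] and [glance()].
#' @export
compare_model_to_observed <- function(predicted, observed, at = c("grid", "knots")) {
  at <- match.arg(at)
  predicted <- one_channel(validate_series(predicted), "predicted")
  observed <- one_channel(validate_series(observed), "observed")
  lo <- max(min(predicted$pd), min(observed$pd))
  hi <- min(max(predicted$pd), max(observed$pd))
  if (lo >= hi) abort("The PD ranges of the two series do not overlap.")
  grid <- if (at == "grid") sort(unique(c(predicted$pd, observed$pd))) else observed$pd
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 3L) abort("Need at least 3 common PDs to compare series.")
  p <- interpolate_series(predicted, grid)
  o <- interpolate_series(observed, grid)
  ## a constant series (flat hTERT-like prediction) has no defined correlation
  r <- if (sd(p) == 0 || sd(o) == 0) NA_real_ else cor(p, o)
  structure(
    list(
      r = r,
      points = tibble(pd = grid, predicted = p, observed = o,
                      residual = o - p),
      at = at
    ),
    class = "series_comparison"
  )
}

#' @export
print.series_comparison <- function(x, ...) {
  cat("Model-observation comparison (", x$at, " mode, ",
      nrow(x$points), " PDs): Pearson r = ", format(x$r), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.series_comparison <- function(x, ...) x$points

#' @export
glance.series_comparison <- function(x, ...) {
  tibble(r = x$r, n = nrow(x$points), at = x$at)
}
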