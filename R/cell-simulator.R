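#' Simulate a population of cells undergoing stochastic step transitions
#'
#' Each simulated cell carries a proliferating phenotype `value_P` drawn
#' from `dist_P`, a senescent phenotype `value_S` drawn from `dist_S`, and
#' a transition PD at which its phenotype steps from `value_P` to
#' `value_S`. Per-cell trajectories are step functions with at most one
#' jump and are never decreasing: `value_S >= value_P` is enforced by
#' redrawing `value_S` from `dist_S` until the constraint holds (bounded
#' rejection sampling, which preserves the shape of `dist_S` in the typical
#' regime where it sits far above `dist_P`). Cells whose transition PD is
#' `Inf` never become senescent (the immortalised, hTERT-like case).
#'
#' Transition PDs can be supplied as:
#' * a [fraction_curve()] — `s(PD)` is treated as the CDF of the transition
#'   PD and inverted by linear interpolation; a cell whose uniform draw
#'   exceeds the curve's maximum never transitions. This makes the
#'   simulated senescent fraction consistent with the curve by construction.
#' * a function `f(n)` returning `n` transition PDs;
#' * a numeric vector of PDs (recycled to `n_cells`); use `Inf` for
#'   immortalised populations.
#'
#' Reproducibility: one master `seed` is expanded into deterministic
#' per-cell substreams, so increasing `n_cells` extends the population
#' without reshuffling earlier cells.
#'
#' @param n_cells Number of cells (`>= 1`).
#' @param dist_P,dist_S [phenotype_dist] objects for the two states.
#' @param transition Transition-PD specification (see Details).
#' @param seed Integer master seed; `NULL` draws one from the session
#'   random stream.
#' @param max_tries Rejection-sampling cap per cell before erroring.
#'
#' @return A tibble of class `cell_population` with columns `cell_id`,
#'   `transition_pd`, `value_P`, `value_S`.
#' @seealso [cell_trace()], [population_summary()]
#' @export
#' @examples
#' cells <- simulate_cells(100, dist_gamma(4, 0.25), dist_gamma(2, 3.3),
#'                         transition = function(n) runif(n, 30, 45), seed = 1)
simulate_cells <- function(n_cells, dist_P, dist_S, transition,
                           seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(dist_P, "phenotype_dist"), inherits(dist_S, "phenotype_dist"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    abort("`n_cells` must be >= 1.")
  }
  n_cells <- as.integer(n_cells)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  trans_fun <- transition_sampler(transition)
  value_P <- numeric(n_cells)
  value_S <- numeric(n_cells)
  transition_pd <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(seed, i))
    transition_pd[i] <- trans_fun(1L)
    value_P[i] <- sample_phenotype(dist_P, 1L)
    vS <- sample_phenotype(dist_S, 1L)
    tries <- 1L
    while (vS < value_P[i]) {
      if (tries >= max_tries) {
        abort(paste0(
          "Could not draw value_S >= value_P after ", max_tries, " attempts ",
          "(cell ", i, "): `dist_S` appears to lie below `dist_P`'s support, ",
          "violating the non-decreasing transition assumption."
        ))
      }
      vS <- sample_phenotype(dist_S, 1L)
      tries <- tries + 1L
    }
    value_S[i] <- vS
  }
  out <- tibble(
    cell_id = seq_len(n_cells),
    transition_pd = transition_pd,
    value_P = value_P,
    value_S = value_S
  )
  class(out) <- c("cell_population", class(out))
  attr(out, "seed") <- seed
  out
}

## deterministic per-cell substream seed below 2^31
cell_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}

## normalise the `transition` argument into a sampler of transition PDs
transition_sampler <- function(transition) {
  if (inherits(transition, "fraction_curve")) {
    s <- transition$s_mean
    pd <- transition$pd
    s_max <- s[length(s)]
    function(n) {
      u <- runif(n)
      out <- rep(Inf, n)
      hit <- u <= s_max
      if (any(hit)) {
        out[hit] <- approx(s, pd, xout = u[hit], ties = "min", rule = 2)$y
      }
      out
    }
  } else if (is.function(transition)) {
    transition
  } else if (is.numeric(transition)) {
    pds <- transition
    idx <- 0L
    function(n) {
      vals <- rep_len(pds, idx + n)[(idx + 1L):(idx + n)]
      idx <<- idx + n
      vals
    }
  } else {
    abort("`transition` must be a fraction_curve, a function, or numeric PDs.")
  }
}

#' Realised per-cell phenotypes over a PD grid
#'
#' Long-format step trajectories: for every cell and every query PD, the
#' realised phenotype is `value_P` before its transition PD and `value_S`
#' from the transition PD on.
#'
#' @param cells A `cell_population` tibble from [simulate_cells()].
#' @param pd_grid Ascending numeric vector of query PDs.
#' @return A tibble with columns `cell_id`, `pd`, `phenotype`, `state`.
#' @export
cell_trace <- function(cells, pd_grid) {
  stopifnot(inherits(cells, "cell_population"))
  if (length(pd_grid) == 0L || is.unsorted(pd_grid)) {
    abort("`pd_grid` must be a non-empty ascending vector.")
  }
  tidyr::crossing(cell_id = cells$cell_id, pd = as.numeric(pd_grid)) |>
    dplyr::left_join(cells, by = "cell_id") |>
    dplyr::mutate(
      state = ifelse(.data$pd >= .data$transition_pd, "senescent", "proliferating"),
      phenotype = ifelse(.data$state == "senescent", .data$value_S, .data$value_P)
    ) |>
    dplyr::select("cell_id", "pd", "phenotype", "state")
}

#' Population summary of a simulated cell population
#'
#' For each query PD: mean and variance of the realised per-cell phenotypes
#' and the realised senescent fraction (proportion of cells with
#' `transition_pd <= pd`).
#'
#' @param cells A `cell_population` tibble from [simulate_cells()].
#' @param pd Numeric vector of query PDs.
#' @return A tibble with columns `pd`, `mean`, `variance`,
#'   `senescent_fraction`.
#' @export
population_summary <- function(cells, pd) {
  stopifnot(inherits(cells, "cell_population"))
  if (nrow(cells) == 0L) abort("`cells` must be non-empty.")
  if (length(pd) == 0L) abort("`pd` must be non-empty.")
  purrr::map_dfr(as.numeric(pd), function(p) {
    sen <- cells$transition_pd <= p
    phen <- ifelse(sen, cells$value_S, cells$value_P)
    tibble(
      pd = p,
      mean = mean(phen),
      variance = if (length(phen) > 1L) var(phen) else 0,
      senescent_fraction = mean(sen)
    )
  })
}
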