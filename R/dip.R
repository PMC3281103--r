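#' Hartigan's dip statistic
#'
#' Distance between the empirical CDF and the nearest unimodal CDF, computed
#' by the greatest-convex-minorant / least-concave-majorant construction of
#' Hartigan & Hartigan with iterative narrowing of the modal interval.
#' The statistic is the final maximal deviation divided by `2n`; it is
#' invariant under affine transformations of the sample and bounded by
#' `1/(2n) <= D <= 1/4` for samples with at least two distinct values.
#' Large values indicate multimodality.
#'
#' The algorithm maintains a candidate modal interval, fits the greatest
#' convex minorant (GCM) of the lower ECDF and the least concave majorant
#' (LCM) of the upper ECDF inside it, finds the largest GCM–LCM gap, records
#' the ECDF deviations from the hulls outside the gap's location, and
#' narrows the interval until the interior gap no longer exceeds the
#' recorded deviation. Ties are handled with the weak-inequality ECDF
#' convention (the unimodal class admits an atom at the mode), with no
#' jittering.
#'
#' @param x Numeric vector with at least 2 finite values.
#' @return The dip statistic (a single number in `[0, 1/4]`).
#' @seealso [dip_test()]
#' @export
#' @examples
#' dip_statistic(c(0, 1))         # 0.25, the maximal value for n = 2
#' dip_statistic(runif(100))
dip_statistic <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) abort("Need at least 2 finite observations for the dip.")
  x <- sort(x)
  if (x[n] == x[1]) return(0)

  ## Predecessor links for the lower convex hull of (x_i, i): GCM shape.
  ## Count differences are identical for upper/lower ECDF, so hull links
  ## are shared; only the evaluation offset differs.
  mn <- integer(n); mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  ## Successor links for the upper concave hull: LCM shape.
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1):1) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L; high <- n
  dip <- 1 # in count units; the returned statistic is dip / (2n)
  repeat {
    if (low >= high) break
    gcm <- high # change points, descending to `low`
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    lcm <- low # change points, ascending to `high`
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    L_g <- length(gcm); L_l <- length(lcm)

    ## Largest gap between LCM (fitted to upper ECDF counts i) and GCM
    ## (fitted to lower counts i - 1), walking both change-point lists
    ## from `low` to `high`.
    ix <- L_g - 1L; iv <- 2L
    d <- 0; ig <- L_g; ih <- 1L
    if (L_g == 2L && L_l == 2L) {
      d <- 1
    } else {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L] # LCM change point inside a GCM segment
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L] # GCM change point inside an LCM segment
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > L_l) iv <- L_l
        if (gcm[ix] == lcm[iv]) break
      }
    }
    if (d < dip) break

    ## Deviations of the ECDF from the hulls outside the new modal interval.
    dip_l <- 0 # upper ECDF above the GCM, low side
    if (ig < L_g) for (j in ig:(L_g - 1L)) {
      je <- gcm[j]; jb <- gcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        jj <- (jb + 1L):(je - 1L)
        dip_l <- max(dip_l, max((jj - jb + 1) - (x[jj] - x[jb]) * C))
      }
    }
    dip_u <- 0 # LCM above the lower ECDF, high side
    if (ih < L_l) for (j in ih:(L_l - 1L)) {
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        jj <- (jb + 1L):(je - 1L)
        dip_u <- max(dip_u, max((x[jj] - x[jb]) * C - (jj - jb) + 1))
      }
    }
    dip <- max(dip, dip_l, dip_u)
    if (gcm[ig] == low && lcm[ih] == high) break
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Bootstrap null distribution of the dip statistic
#'
#' Dip statistics of `n_boot` uniform(0, 1) samples of size `n` — the
#' conventional reference null of the dip test (the uniform is the
#' asymptotically least favourable unimodal distribution). The null
#' distribution depends only on `n`, so a table can be computed once and
#' reused across many tests of the same sample size.
#'
#' Uses the global R random stream; call `set.seed()` for reproducibility.
#'
#' @param n Sample size of each null draw.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @return Numeric vector of `n_boot` dip statistics.
#' @export
dip_null_table <- function(n, n_boot = 2000) {
  stopifnot(n >= 2, n_boot >= 1)
  vapply(seq_len(n_boot), function(i) dip_statistic(runif(n)), 0)
}

#' Hartigan's dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution. The p-value is the proportion of bootstrap dip statistics
#' (same `n`, uniform null, see [dip_null_table()]) that reach or exceed
#' the observed statistic, with the `+1/(n_boot + 1)` continuity correction,
#' so it always lies in `(0, 1]`.
#'
#' @param x Numeric sample (at least 10 values).
#' @param n_boot Number of bootstrap replicates (at least 100; default 2000).
#' @param null_stats Optional precomputed vector of null dip statistics for
#'   this sample size (from [dip_null_table()]); when supplied, `n_boot` is
#'   ignored and no new bootstrap is run.
#' @return An object of class `dip_test` with fields `statistic`,
#'   `p_value`, `n`, `n_boot`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' set.seed(1)
#' dip_test(rgamma(500, 4), n_boot = 200)
dip_test <- function(x, n_boot = 2000, null_stats = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) abort("Need at least 10 observations for the dip test.")
  stat <- dip_statistic(x)
  if (is.null(null_stats)) {
    if (n_boot < 100) abort("`n_boot` must be at least 100.")
    null_stats <- dip_null_table(length(x), n_boot)
  }
  nb <- length(null_stats)
  p <- (sum(null_stats >= stat) + 1) / (nb + 1)
  structure(
    list(statistic = stat, p_value = p, n = length(x), n_boot = nb),
    class = "dip_test"
  )
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigan dip test of unimodality\n")
  cat("  D = ", format(x$statistic), ", n = ", x$n,
      ", bootstrap p = ", format(x$p_value),
      " (", x$n_boot, " uniform replicates)\n", sep = "")
  invisible(x)
}

#' @export
tidy.dip_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n = x$n, n.boot = x$n_boot,
         method = "Hartigan dip test (uniform bootstrap)")
}

#' @export
glance.dip_test <- function(x, ...) tidy(x)
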