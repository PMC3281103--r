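#' Classify cells by senescence markers
#'
#' Assigns each cell to one of three categories from its proliferation
#' marker (Ki67) and DNA-damage foci count (gamma-H2A.X):
#'
#' * `KI67_POS` — Ki67-positive (cycling), regardless of foci;
#' * `KI67_NEG_HIGH_FOCI` — Ki67-negative with more than 5 foci per
#'   nucleus, the quantitative senescence criterion;
#' * `KI67_NEG_LOW_FOCI` — Ki67-negative with 5 or fewer foci.
#'
#' A count of exactly 5 foci goes to the low-foci group: the senescence
#' criterion is strictly "more than 5 foci per nucleus".
#'
#' @param records A data frame with columns `ki67_positive` (logical or
#'   0/1) and `foci_count` (non-negative integers); typically also
#'   `cell_id`, `pd`, `mitosox`.
#' @return The input as a tibble with a `category` factor column appended.
#' @export
#' @examples
#' classify_cells(data.frame(ki67_positive = c(1, 0, 0), foci_count = c(12, 6, 0)))
classify_cells <- function(records) {
  need <- c("ki67_positive", "foci_count")
  if (!all(need %in% names(records))) {
    abort("`records` must have columns `ki67_positive` and `foci_count`.")
  }
  records <- as_tibble(records)
  foci <- records$foci_count
  if (anyNA(foci) || any(foci < 0) || any(foci != round(foci))) {
    abort("`foci_count` must be non-negative integers.")
  }
  ki <- as.logical(records$ki67_positive)
  if (anyNA(ki)) abort("`ki67_positive` must be logical or 0/1 without NA.")
  if ("mitosox" %in% names(records) &&
      (anyNA(records$mitosox) || any(records$mitosox < 0))) {
    abort("`mitosox` must be non-negative without NA.")
  }
  records$category <- factor(
    dplyr::case_when(
      ki ~ "KI67_POS",
      foci > 5 ~ "KI67_NEG_HIGH_FOCI",
      TRUE ~ "KI67_NEG_LOW_FOCI"
    ),
    levels = c("KI67_POS", "KI67_NEG_LOW_FOCI", "KI67_NEG_HIGH_FOCI")
  )
  records
}

#' Summarise MitoSOX by marker category and test group differences
#'
#' Produces per-category summaries of the MitoSOX intensity (n, mean, sd,
#' quartiles) and a two-factor analysis of variance (category and PD) with
#' Tukey pairwise contrasts. The senescent high-foci group is flagged when
#' its mean exceeds both other group means and both pairwise comparisons
#' against it are significant at `alpha`.
#'
#' Categories with fewer than 2 cells are excluded with a warning. At least
#' two non-empty categories are required.
#'
#' @param records A data frame with columns `mitosox`, `pd` and either a
#'   `category` column or the marker columns consumed by
#'   [classify_cells()].
#' @param alpha Significance level for the flag (default 0.05).
#' @return An object of class `marker_summary` with elements `summary`
#'   (per-category tibble), `anova` (the [stats::aov] fit), `contrasts`
#'   (Tukey category contrasts), `high_foci_flag` and `alpha`. Supports
#'   [tidy()] and [glance()].
#' @export
group_summary <- function(records, alpha = 0.05) {
  if (!"category" %in% names(records)) records <- classify_cells(records)
  if (!all(c("mitosox", "pd") %in% names(records))) {
    abort("`records` must have columns `mitosox` and `pd`.")
  }
  records <- as_tibble(records)
  counts <- table(droplevels(records$category))
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warn(paste0("Excluding categories with n < 2: ", paste(small, collapse = ", ")))
    records <- records[!records$category %in% small, , drop = FALSE]
  }
  records$category <- droplevels(records$category)
  if (nlevels(records$category) < 2L) {
    abort("Need at least 2 non-empty categories to compare groups.")
  }

  summary_tbl <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$mitosox),
      sd = stats::sd(.data$mitosox),
      q25 = quantile(.data$mitosox, 0.25),
      median = stats::median(.data$mitosox),
      q75 = quantile(.data$mitosox, 0.75),
      .groups = "drop"
    )

  ## two-factor ANOVA; the PD factor drops out automatically when all cells
  ## share one PD
  records$pd_f <- factor(records$pd)
  form <- if (nlevels(records$pd_f) > 1L) {
    mitosox ~ category + pd_f
  } else {
    mitosox ~ category
  }
  fit <- aov(form, data = records)
  tk <- TukeyHSD(fit, which = "category")$category

  flag <- FALSE
  if ("KI67_NEG_HIGH_FOCI" %in% levels(records$category)) {
    hi_mean <- summary_tbl$mean[summary_tbl$category == "KI67_NEG_HIGH_FOCI"]
    others <- summary_tbl[summary_tbl$category != "KI67_NEG_HIGH_FOCI", ]
    hits <- grepl("KI67_NEG_HIGH_FOCI", rownames(tk))
    flag <- all(hi_mean > others$mean) &&
      sum(hits) >= 1 && all(tk[hits, "p adj"] < alpha)
  }

  structure(
    list(summary = summary_tbl, anova = fit,
         contrasts = as.data.frame(tk), high_foci_flag = flag, alpha = alpha),
    class = "marker_summary"
  )
}

#' @export
print.marker_summary <- function(x, ...) {
  cat("MitoSOX by marker category\n")
  print(x$summary)
  cat("High-foci senescent group significantly above both others: ",
      x$high_foci_flag, " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.marker_summary <- function(x, ...) x$summary

#' @export
glance.marker_summary <- function(x, ...) {
  tibble(n_groups = nrow(x$summary), n_cells = sum(x$summary$n),
         high_foci_flag = x$high_foci_flag, alpha = x$alpha)
}
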