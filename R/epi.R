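#' Registry metrics of ESRD attributable to IgAN
#'
#' Derives, per region, the three prevalence definitions plus incidence:
#' IgAN-ESRD cases per million population (prevalence PMP), incident
#' IgAN-ESRD cases per million population over the reporting period
#' (incidence PMP), the percentage of all ESRD cases attributable to
#' IgAN, and the percentage of primary-glomerulonephritis ESRD
#' attributable to IgAN. Metrics with a zero denominator are `NA`.
#'
#' @param records prevalence table from [read_prevalence_table()].
#' @return `data.frame` with columns `region_name`, `average_latitude`,
#'   `incidence_pmp`, `prevalence_pmp`, `pct_esrd`, `pct_gn_esrd`.
#' @export
epi_metrics <- function(records) {
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    region_name = records$region_name,
    average_latitude = records$average_latitude,
    incidence_pmp = div(records$incident_count, records$population_millions),
    prevalence_pmp = div(records$prevalent_count, records$population_millions),
    pct_esrd = 100 * div(records$prevalent_count, records$total_esrd_count),
    pct_gn_esrd = 100 * div(records$prevalent_count, records$gn_esrd_count),
    stringsAsFactors = FALSE
  )
}

#' Fold-ratios of registry metrics between groups
#'
#' Expresses each region's (here typically ethnicity's) metrics relative
#' to a reference region, e.g. the fold-difference in the percentage of
#' ESRD attributable to IgAN between Asian Americans and African
#' Americans.
#'
#' @param metrics output of [epi_metrics()].
#' @param reference `region_name` used as denominator.
#' @return `data.frame` of fold-ratios (reference row = 1).
#' @export
ethnic_fold_ratio <- function(metrics, reference) {
  i <- match(reference, metrics$region_name)
  if (is.na(i)) stop("reference group not found: ", reference)
  cols <- c("incidence_pmp", "prevalence_pmp", "pct_esrd", "pct_gn_esrd")
  out <- metrics[, c("region_name", cols)]
  for (cl in cols) out[[cl]] <- out[[cl]] / metrics[[cl]][i]
  out
}

#' Latitude regression of registry metrics and genetic risk
#'
#' Pearson correlation (two-sided) and least-squares line of each
#' registry metric -- and optionally of per-region median risk scores --
#' against average region latitude.
#'
#' @param metrics output of [epi_metrics()] (needs `average_latitude`).
#' @param scores optional named vector of per-region median standardised
#'   risk scores (names matching `region_name`).
#' @return `data.frame` with one row per metric: `metric`, `r`, `p`,
#'   `intercept`, `slope`, `n`.
#' @export
latitude_regression <- function(metrics, scores = NULL) {
  if (nrow(metrics) < 3) stop("need at least 3 regions")
  cols <- c("incidence_pmp", "prevalence_pmp", "pct_esrd", "pct_gn_esrd")
  tabs <- lapply(cols, function(cl) {
    ok <- is.finite(metrics[[cl]])
    x <- metrics$average_latitude[ok]; y <- metrics[[cl]][ok]
    if (sum(ok) < 3 || stats::sd(y) == 0)
      stop("degenerate metric ", cl)
    ct <- stats::cor.test(x, y, method = "pearson")
    ln <- stats::lm(y ~ x)
    data.frame(metric = cl, r = unname(ct$estimate), p = ct$p.value,
               intercept = unname(stats::coef(ln)[1]),
               slope = unname(stats::coef(ln)[2]), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  if (!is.null(scores)) {
    i <- match(metrics$region_name, names(scores))
    ok <- !is.na(i)
    x <- metrics$average_latitude[ok]; y <- scores[i[ok]]
    ct <- stats::cor.test(x, y, method = "pearson")
    ln <- stats::lm(y ~ x)
    out <- rbind(out, data.frame(
      metric = "median_risk_score", r = unname(ct$estimate), p = ct$p.value,
      intercept = unname(stats::coef(ln)[1]),
      slope = unname(stats::coef(ln)[2]), n = sum(ok),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
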