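#' Cochran-Armitage trend test
#'
#' One-degree-of-freedom test for a dose-response association between
#' counted-allele dosage and case status, with additive scores (0, 1, 2).
#'
#' @param case_counts,control_counts length-3 genotype counts
#'   `(n0, n1, n2)` for dosages 0/1/2.
#' @return `list(statistic, p_value)`; a monomorphic table yields
#'   statistic 0 and p = 1 with a warning.
#' @export
trend_test <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3)
  s <- 0:2
  n_g <- case_counts + control_counts
  R <- sum(case_counts); N <- sum(n_g)
  if (R == 0 || R == N) stop("both cases and controls are required")
  num <- N * sum(s * case_counts) - R * sum(s * n_g)
  den <- R * (N - R) * (N * sum(s^2 * n_g) - sum(s * n_g)^2)
  if (den <= 0) {
    warning("monomorphic table: trend statistic undefined, returning p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  stat <- N * num^2 / den
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Per-allele odds ratio with Woolf confidence interval
#'
#' 2x2 allele-count odds ratio `ad/bc` with the Woolf (log) standard
#' error; the Haldane continuity correction of 0.5 is added to every cell
#' if and only if some cell is zero.
#'
#' @param case_alleles,control_alleles length-2 counts
#'   `(counted, other)` alleles in cases and controls.
#' @param conf_level confidence level (default 0.95).
#' @return `list(or, log_or, se, ci)` where `ci` is the two-sided interval
#'   on the OR scale.
#' @export
allelic_or <- function(case_alleles, control_alleles, conf_level = 0.95) {
  stopifnot(length(case_alleles) == 2, length(control_alleles) == 2)
  a <- case_alleles[1]; b <- case_alleles[2]
  c_ <- control_alleles[1]; d <- control_alleles[2]
  if ((a == 0 && b == 0) || (c_ == 0 && d == 0) ||
      (a == 0 && c_ == 0) || (b == 0 && d == 0))
    stop("two zero cells share a margin: odds ratio undefined")
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or), log_or = log_or, se = se,
       ci = exp(log_or + c(-1, 1) * z * se))
}

#' Per-cohort single-SNP association
#'
#' Runs the Cochran-Armitage trend test and computes the per-allele odds
#' ratio for every SNP within every cohort.
#'
#' @param data a [genotype_dataset()].
#' @return `data.frame` with one row per SNP x cohort: counted-allele
#'   counts, trend statistic and p, log OR, SE and 95% CI.
#' @export
cohort_association <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  rows <- list()
  for (co in unique(data$individuals$cohort)) {
    in_co <- data$individuals$cohort == co
    is_case <- data$individuals$phenotype == "case"
    for (j in seq_len(ncol(data$genotypes))) {
      gca <- data$genotypes[in_co & is_case, j]
      gco <- data$genotypes[in_co & !is_case, j]
      gca <- gca[!is.na(gca)]; gco <- gco[!is.na(gco)]
      cc <- tabulate(gca + 1L, 3L); kk <- tabulate(gco + 1L, 3L)
      tt <- trend_test(cc, kk)
      orr <- allelic_or(c(sum(gca), 2 * length(gca) - sum(gca)),
                        c(sum(gco), 2 * length(gco) - sum(gco)))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = data$snps$snp_id[j], cohort = co,
        case_allele_count = sum(gca), case_n = length(gca),
        control_allele_count = sum(gco), control_n = length(gco),
        trend_stat = tt$statistic, trend_p = tt$p_value,
        log_or = orr$log_or, se = orr$se,
        ci_lower = orr$ci[1], ci_upper = orr$ci[2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
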