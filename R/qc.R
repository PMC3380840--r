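#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided p-value for a biallelic genotype count triple, computed
#' by enumerating all heterozygote counts compatible with the observed
#' allele counts and summing the conditional probabilities no larger than
#' that of the observed configuration (the standard exact HWE test used for
#' genotyping quality control; preferred over the chi-square approximation
#' for small cohorts).
#'
#' @param n_aa,n_ab,n_bb genotype counts (counted-allele homozygote,
#'   heterozygote, other homozygote).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2L * n_aa + n_ab         # rarer-or-not allele count, symmetric below
  if (n_a > n) n_a <- 2L * n - n_a
  # log-probabilities of every possible heterozygote count given allele counts
  het <- seq.int(n_a %% 2L, n_a, by = 2L)
  lp <- vapply(het, function(h) {
    a <- (n_a - h) / 2; b <- n - (n_a + h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(2 * n - n_a + 1))
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- n_ab  # heterozygote count is invariant under allele relabelling
  min(1, sum(p[p <= p[match(obs, het)] * (1 + 1e-12)]))
}

#' Genotype and sample quality-control filter
#'
#' Applies the replication-study thresholds within each case-control
#' cohort separately, then intersects: a SNP is removed if in \emph{any}
#' cohort its minor allele frequency is not above `maf_min`, its
#' missingness is not below `snp_miss_max`, or its exact HWE p-value in
#' that cohort's controls is not above `hwe_p_min`. Individuals with more
#' than `indiv_miss_max` missing genotypes are removed first.
#'
#' @param data a [genotype_dataset()].
#' @param maf_min minor allele frequency threshold (pass requires
#'   MAF > `maf_min`; default 0.01).
#' @param snp_miss_max per-SNP missingness threshold (pass requires
#'   missingness < `snp_miss_max`; default 0.05).
#' @param hwe_p_min exact HWE p-value threshold in controls (pass requires
#'   p > `hwe_p_min`; default 0.01).
#' @param indiv_miss_max maximum tolerated missing genotypes per
#'   individual (default 2).
#' @return `list(data, report)`: the filtered dataset and a `qc_report`
#'   with per-SNP-per-cohort and per-individual tables listing every
#'   exclusion with its reason.
#' @export
qc_filter <- function(data, maf_min = 0.01, snp_miss_max = 0.05,
                      hwe_p_min = 0.01, indiv_miss_max = 2) {
  stopifnot(inherits(data, "genotype_dataset"))
  miss_count <- rowSums(is.na(data$genotypes))
  ind_report <- data.frame(
    individual_id = data$individuals$individual_id,
    n_missing = miss_count,
    pass = miss_count <= indiv_miss_max
  )
  data <- subset_dataset(data, individuals = which(ind_report$pass))

  cohorts <- unique(data$individuals$cohort)
  rows <- list()
  for (co in cohorts) {
    in_co <- data$individuals$cohort == co
    is_ctl <- in_co & data$individuals$phenotype == "control"
    if (!any(is_ctl))
      stop("cohort ", co, " has no controls; HWE cannot be assessed")
    for (j in seq_len(ncol(data$genotypes))) {
      g <- data$genotypes[in_co, j]
      miss <- mean(is.na(g))
      f <- mean(g, na.rm = TRUE) / 2
      maf <- min(f, 1 - f)
      gc <- data$genotypes[is_ctl, j]
      gc <- gc[!is.na(gc)]
      hwe_p <- if (length(gc)) {
        hwe_exact_test(sum(gc == 2L), sum(gc == 1L), sum(gc == 0L))
      } else NA_real_
      reason <- character()
      if (is.nan(maf) || maf <= maf_min) reason <- c(reason, "maf")
      if (miss >= snp_miss_max) reason <- c(reason, "missingness")
      if (!is.na(hwe_p) && hwe_p <= hwe_p_min) reason <- c(reason, "hwe")
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = data$snps$snp_id[j], cohort = co, maf = maf,
        missingness = miss, hwe_p_controls = hwe_p,
        pass = !length(reason),
        reason = if (length(reason)) paste(reason, collapse = "+") else "",
        stringsAsFactors = FALSE
      )
    }
  }
  snp_report <- do.call(rbind, rows)
  keep_snp <- !(data$snps$snp_id %in% snp_report$snp_id[!snp_report$pass])
  if (!any(keep_snp)) stop("no SNPs survive quality control")
  data <- subset_dataset(data, snps = which(keep_snp))
  report <- structure(
    list(snp = snp_report, individual = ind_report,
         thresholds = c(maf_min = maf_min, snp_miss_max = snp_miss_max,
                        hwe_p_min = hwe_p_min, indiv_miss_max = indiv_miss_max)),
    class = "qc_report"
  )
  list(data = data, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d SNP-cohort cells pass, %d/%d individuals pass\n",
              sum(x$snp$pass), nrow(x$snp),
              sum(x$individual$pass), nrow(x$individual)))
  invisible(x)
}
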