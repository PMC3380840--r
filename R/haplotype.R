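#' EM haplotype frequency estimation from unphased genotypes
#'
#' Expectation-maximisation over the `2^k` haplotypes of a small SNP
#' subset. Individuals with a missing genotype in the subset are excluded.
#' The log-likelihood is non-decreasing across iterations; the run is
#' repeated from a product-of-allele-frequencies start plus `restarts`
#' random Dirichlet starts (use the caller's RNG seed for reproducibility)
#' and the best likelihood is kept.
#'
#' @param geno dosage matrix (individuals x SNPs, values 0/1/2) or a
#'   [genotype_dataset()] together with `snp_ids`.
#' @param snp_ids SNP subset (<= 8 SNPs) when `geno` is a dataset.
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @param restarts number of extra random starts (default 10).
#' @return `list(freq, posterior, log_lik, n)`: haplotype frequency
#'   vector named by allele string (counted allele at each site for bit 1),
#'   per-individual posterior diplotype weights, the final log-likelihood
#'   and the number of phased individuals.
#' @export
em_phase <- function(geno, snp_ids = NULL, tol = 1e-8, max_iter = 1000,
                     restarts = 10) {
  alleles <- NULL
  if (inherits(geno, "genotype_dataset")) {
    stopifnot(!is.null(snp_ids))
    idx <- match(snp_ids, geno$snps$snp_id)
    alleles <- geno$snps[idx, c("counted_allele", "other_allele")]
    geno <- dosages(geno, snp_ids)
  }
  geno <- as.matrix(geno)
  k <- ncol(geno)
  if (k > 8) stop("haplotype enumeration limited to 8 SNPs")
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  n <- nrow(geno)
  if (n == 0) stop("no informative individuals")

  haps <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  hap_key <- apply(haps, 1, paste, collapse = "")
  nh <- nrow(haps)

  # collapse identical genotype rows; enumerate compatible diplotypes once
  gkey <- apply(geno, 1, paste, collapse = "")
  ug <- !duplicated(gkey)
  ugeno <- geno[ug, , drop = FALSE]
  counts <- as.numeric(table(gkey)[apply(ugeno, 1, paste, collapse = "")])
  pairs <- lapply(seq_len(nrow(ugeno)), function(i) {
    g <- ugeno[i, ]
    het <- which(g == 1L)
    base <- integer(k); base[g == 2L] <- 1L
    if (!length(het)) {
      h <- sum(base * 2^(seq_len(k) - 1))  # index into haps via bit value
      return(cbind(h1 = h, h2 = h))
    }
    picks <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    h1 <- vapply(seq_len(nrow(picks)), function(r) {
      v <- base; v[het] <- picks[r, ]
      sum(v * 2^(seq_len(k) - 1))
    }, numeric(1))
    h2 <- vapply(seq_len(nrow(picks)), function(r) {
      v <- base; v[het] <- 1L - picks[r, ]
      sum(v * 2^(seq_len(k) - 1))
    }, numeric(1))
    keep <- h1 <= h2
    cbind(h1 = h1[keep], h2 = h2[keep])
  })
  # map bit values to row indices of `haps`
  bit_of <- apply(haps, 1, function(h) sum(h * 2^(seq_len(k) - 1)))
  row_of <- match(seq_len(nh) - 1L, bit_of)
  pairs <- lapply(pairs, function(pp)
    cbind(h1 = row_of[pp[, 1] + 1L], h2 = row_of[pp[, 2] + 1L]))

  run_em <- function(f) {
    ll_old <- -Inf; trace <- numeric()
    for (it in seq_len(max_iter)) {
      expect <- numeric(nh); ll <- 0
      for (i in seq_along(pairs)) {
        pp <- pairs[[i]]
        w <- f[pp[, 1]] * f[pp[, 2]] * ifelse(pp[, 1] == pp[, 2], 1, 2)
        tot <- sum(w)
        if (tot <= 0) return(list(f = f, ll = -Inf, trace = trace))
        w <- w / tot
        ll <- ll + counts[i] * log(tot)
        inc <- counts[i] * w
        expect[pp[, 1]] <- expect[pp[, 1]] + inc
        expect[pp[, 2]] <- expect[pp[, 2]] + inc
      }
      f <- expect / (2 * n)
      trace <- c(trace, ll)
      if (ll - ll_old < tol && it > 1) break
      ll_old <- ll
    }
    list(f = f, ll = ll, trace = trace)
  }

  af <- colMeans(geno) / 2
  f0 <- apply(haps, 1, function(h) prod(ifelse(h == 1, af, 1 - af)))
  best <- run_em(f0 / sum(f0))
  for (r in seq_len(restarts)) {
    fr <- stats::rgamma(nh, 1); fr <- fr / sum(fr)
    cand <- run_em(fr)
    if (cand$ll > best$ll + 1e-10) best <- cand
  }
  f <- best$f / sum(best$f)

  # posterior diplotype weights per unique genotype, expanded to individuals
  post_u <- lapply(pairs, function(pp) {
    w <- f[pp[, 1]] * f[pp[, 2]] * ifelse(pp[, 1] == pp[, 2], 1, 2)
    data.frame(hap1 = hap_key[pp[, 1]], hap2 = hap_key[pp[, 2]],
               weight = w / sum(w), stringsAsFactors = FALSE)
  })
  names(post_u) <- apply(ugeno, 1, paste, collapse = "")
  posterior <- post_u[gkey]

  key <- hap_key
  if (!is.null(alleles)) {
    key <- apply(haps, 1, function(h)
      paste(ifelse(h == 1, alleles$counted_allele, alleles$other_allele),
            collapse = ""))
  }
  list(freq = stats::setNames(f, key), posterior = posterior,
       log_lik = best$ll, log_lik_trace = best$trace, n = n)
}

#' Haplotype association table with reference-relative odds ratios
#'
#' Works from group-wise haplotype frequencies and group sizes (as
#' produced by separate case/control EM runs, or transcribed estimates).
#' The overall frequency is the chromosome-count weighted average; only
#' common haplotypes (overall frequency above `common_threshold`) are
#' tested. The OR of haplotype h against the reference r is the
#' frequency-ratio estimator `(f_case,h / f_case,r) / (f_ctl,h / f_ctl,r)`
#' with a Woolf interval on expected haplotype counts, and the global test
#' is a chi-square over the common-haplotype expected count table with
#' `n_common - 1` degrees of freedom.
#'
#' @param freq_cases,freq_controls named haplotype frequency vectors.
#' @param n_cases,n_controls number of individuals per group (2n
#'   chromosomes each).
#' @param reference reference haplotype (default: highest overall
#'   frequency); must be common.
#' @param common_threshold overall-frequency cutoff (default 0.01).
#' @return A `haplotype_table` data frame (one row per common haplotype)
#'   with attributes `global_chisq`, `global_df`, `global_p`, `reference`.
#' @export
haplotype_association <- function(freq_cases, freq_controls, n_cases,
                                  n_controls, reference = NULL,
                                  common_threshold = 0.01) {
  all_h <- union(names(freq_cases), names(freq_controls))
  fc <- stats::setNames(numeric(length(all_h)), all_h)
  ft <- fc
  fc[names(freq_cases)] <- freq_cases
  ft[names(freq_controls)] <- freq_controls
  overall <- (n_cases * fc + n_controls * ft) / (n_cases + n_controls)
  common <- names(overall)[overall > common_threshold]
  if (is.null(reference)) reference <- names(which.max(overall))
  if (!reference %in% common)
    stop("reference haplotype ", reference, " is below the common threshold")
  ord <- common[order(-overall[common])]
  cc <- 2 * n_cases; ct <- 2 * n_controls
  rows <- lapply(ord, function(h) {
    if (h == reference) {
      return(data.frame(haplotype = h, freq_overall = overall[h],
                        freq_cases = fc[h], freq_controls = ft[h],
                        or = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                        stringsAsFactors = FALSE))
    }
    orr <- allelic_or(c(fc[h] * cc, fc[reference] * cc),
                      c(ft[h] * ct, ft[reference] * ct))
    data.frame(haplotype = h, freq_overall = overall[h],
               freq_cases = fc[h], freq_controls = ft[h],
               or = orr$or, ci_lower = orr$ci[1], ci_upper = orr$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  obs <- rbind(cases = fc[ord] * cc, controls = ft[ord] * ct)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chisq <- sum((obs - expd)^2 / expd)
  df <- length(ord) - 1L
  structure(out, class = c("haplotype_table", "data.frame"),
            global_chisq = chisq, global_df = df,
            global_p = stats::pchisq(chisq, df, lower.tail = FALSE),
            reference = reference)
}

#' Phase a SNP subset and test haplotype association
#'
#' Runs [em_phase()] separately in cases and controls (the group-specific
#' frequency estimates) and feeds the results to
#' [haplotype_association()].
#'
#' @param data a [genotype_dataset()].
#' @param snp_ids SNP subset to phase.
#' @param ... passed on to [haplotype_association()].
#' @return A `haplotype_table`.
#' @export
haplotype_analysis <- function(data, snp_ids, ...) {
  stopifnot(inherits(data, "genotype_dataset"))
  is_case <- data$individuals$phenotype == "case"
  em_ca <- em_phase(subset_dataset(data, individuals = which(is_case)),
                    snp_ids)
  em_co <- em_phase(subset_dataset(data, individuals = which(!is_case)),
                    snp_ids)
  haplotype_association(em_ca$freq, em_co$freq,
                        n_cases = em_ca$n, n_controls = em_co$n, ...)
}
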