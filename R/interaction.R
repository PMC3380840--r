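#' Cordell-Clayton genotype coding
#'
#' Maps a counted-allele dosage to the allelic and dominance components
#' used in the genotypic interaction test: genotypes AA, AB, BB (dosage
#' 0, 1, 2) are coded `x_a = -1, 0, 1` and `x_d = -0.5, 0.5, -0.5`.
#'
#' @param dosage vector of dosages in `{0, 1, 2}` (no missing values).
#' @return `data.frame(x_a, x_d)`.
#' @export
cordell_clayton_code <- function(dosage) {
  if (anyNA(dosage)) stop("missing dosages must be excluded upstream")
  stopifnot(all(dosage %in% 0:2))
  data.frame(x_a = dosage - 1, x_d = ifelse(dosage == 1L, 0.5, -0.5))
}

# shared scaffolding: pairwise-complete design pieces for a SNP pair
pair_design <- function(data, snp_a, snp_b, cohort_covariate) {
  ga <- dosages(data, snp_a)[, 1]
  gb <- dosages(data, snp_b)[, 1]
  keep <- !is.na(ga) & !is.na(gb)
  y <- as.integer(data$individuals$phenotype == "case")[keep]
  cohort <- factor(data$individuals$cohort[keep])
  use_cohort <- isTRUE(cohort_covariate) && nlevels(cohort) > 1
  list(y = y, ga = ga[keep], gb = gb[keep],
       cohort = if (use_cohort) cohort else NULL)
}

fit_ll <- function(y, X, cohort) {
  df <- data.frame(y = y, X, check.names = FALSE)
  form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  if (!is.null(cohort)) {
    df$.cohort <- cohort
    form <- stats::update(form, . ~ . + .cohort)
  }
  fit <- stats::glm(form, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge")
  fit
}

#' Multiplicative (1-df) interaction likelihood-ratio test
#'
#' Compares nested logistic models with main dosage effects only versus
#' main effects plus the dosage-product interaction term; the LRT
#' statistic is referred to chi-square with 1 df. Cohort indicators enter
#' both models. Individuals missing either SNP are excluded pairwise.
#'
#' @param data a [genotype_dataset()].
#' @param snp_a,snp_b the SNP pair.
#' @param cohort_covariate include cohort fixed effects (default `TRUE`).
#' @return `list(snp_a, snp_b, lrt, p_1df, beta_int, se_int, n)`.
#' @export
multiplicative_lrt <- function(data, snp_a, snp_b, cohort_covariate = TRUE) {
  d <- pair_design(data, snp_a, snp_b, cohort_covariate)
  X0 <- cbind(a = d$ga, b = d$gb)
  colnames(X0) <- c(snp_a, snp_b)
  X1 <- cbind(X0, int = d$ga * d$gb)
  colnames(X1)[3] <- paste0(snp_a, ":", snp_b)
  f0 <- fit_ll(d$y, X0, d$cohort)
  f1 <- fit_ll(d$y, X1, d$cohort)
  lrt <- max(0, as.numeric(2 * (stats::logLik(f1) - stats::logLik(f0))))
  cf <- summary(f1)$coefficients
  i <- match(sprintf("`%s:%s`", snp_a, snp_b), rownames(cf))
  if (is.na(i)) i <- match(paste0(snp_a, ":", snp_b), rownames(cf))
  list(snp_a = snp_a, snp_b = snp_b, lrt = lrt,
       p_1df = stats::pchisq(lrt, 1, lower.tail = FALSE),
       beta_int = cf[i, 1], se_int = cf[i, 2], n = length(d$y))
}

#' Genotypic (4-df) interaction test
#'
#' Cordell-Clayton coding for both SNPs: the full model carries allelic
#' and dominance effects of each SNP plus their four cross products; the
#' reduced model drops the products. The LRT is referred to chi-square
#' with 4 df.
#'
#' @inheritParams multiplicative_lrt
#' @return `list(lrt, p_4df, n)`.
#' @export
genotypic_4df_test <- function(data, snp_a, snp_b, cohort_covariate = TRUE) {
  d <- pair_design(data, snp_a, snp_b, cohort_covariate)
  ca <- cordell_clayton_code(d$ga)
  cb <- cordell_clayton_code(d$gb)
  X0 <- cbind(aa = ca$x_a, ad = ca$x_d, ba = cb$x_a, bd = cb$x_d)
  X1 <- cbind(X0,
              ii_aa = ca$x_a * cb$x_a, ii_ad = ca$x_a * cb$x_d,
              ii_da = ca$x_d * cb$x_a, ii_dd = ca$x_d * cb$x_d)
  cell <- table(d$ga, d$gb)
  f0 <- tryCatch(fit_ll(d$y, X0, d$cohort), error = function(e)
    stop("reduced genotypic model failed (genotype cells: ",
         paste(as.vector(cell), collapse = ","), "): ", conditionMessage(e)))
  f1 <- tryCatch(fit_ll(d$y, X1, d$cohort), error = function(e)
    stop("full genotypic model failed (genotype cells: ",
         paste(as.vector(cell), collapse = ","), "): ", conditionMessage(e)))
  if (anyNA(stats::coef(f1)))
    stop("sparse genotype cells: full genotypic model is rank deficient ",
         "(cells: ", paste(as.vector(cell), collapse = ","), ")")
  lrt <- max(0, as.numeric(2 * (stats::logLik(f1) - stats::logLik(f0))))
  list(lrt = lrt, p_4df = stats::pchisq(lrt, 4, lower.tail = FALSE),
       n = length(d$y))
}

#' Exhaustive first-order interaction screen
#'
#' Tests every SNP pair with the 1-df multiplicative LRT (and the 4-df
#' genotypic test) and flags significance at the Bonferroni threshold
#' `0.05 / choose(k, 2)`.
#'
#' @param data a [genotype_dataset()].
#' @param snp_ids SNPs to screen (k >= 2; the replication screen used 7,
#'   giving 21 pairs and threshold 0.05/21 = 2.4e-3).
#' @param cohort_covariate include cohort fixed effects (default `TRUE`).
#' @param genotypic also run the 4-df test per pair (default `FALSE`,
#'   matching the two-stage procedure in which the genotypic test is a
#'   follow-up on screen-significant pairs); a pair whose genotypic model
#'   cannot be fitted (sparse cells) gets `NA`.
#' @return `data.frame`, one row per pair, with `beta_int`, `p_1df`,
#'   optional `p_4df`, and a `significant` flag; the threshold is stored
#'   in `attr(, "bonferroni")`.
#' @export
interaction_screen <- function(data, snp_ids, cohort_covariate = TRUE,
                               genotypic = FALSE) {
  stopifnot(length(snp_ids) >= 2)
  prs <- utils::combn(snp_ids, 2)
  thr <- 0.05 / ncol(prs)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    m <- multiplicative_lrt(data, a, b, cohort_covariate)
    out <- data.frame(snp_a = a, snp_b = b, beta_int = m$beta_int,
                      se_int = m$se_int, lrt = m$lrt, p_1df = m$p_1df,
                      stringsAsFactors = FALSE)
    if (genotypic)
      out$p_4df <- tryCatch(
        genotypic_4df_test(data, a, b, cohort_covariate)$p_4df,
        error = function(e) NA_real_)
    out
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_1df < thr
  attr(out, "bonferroni") <- thr
  out
}

#' Stratified allelic effects of one SNP by genotype class of another
#'
#' For each genotype class (dosage 0/1/2) of `snp_b` with at least
#' `min_stratum` individuals, fits the logistic allelic effect of `snp_a`
#' with a 95% confidence interval (the display underlying
#' interaction-reversal figures).
#'
#' @inheritParams multiplicative_lrt
#' @param min_stratum smallest stratum analysed (default 10).
#' @return `data.frame` with one row per available stratum: `stratum`,
#'   `n`, `log_or`, `se`, `ci_lower`, `ci_upper`.
#' @export
stratum_effects <- function(data, snp_a, snp_b, cohort_covariate = TRUE,
                            min_stratum = 10) {
  d <- pair_design(data, snp_a, snp_b, cohort_covariate)
  rows <- list()
  for (g in 0:2) {
    in_g <- d$gb == g
    n <- sum(in_g)
    if (n < min_stratum) next
    X <- cbind(a = d$ga[in_g]); colnames(X) <- snp_a
    co_g <- if (!is.null(d$cohort)) droplevels(d$cohort[in_g]) else NULL
    if (!is.null(co_g) && nlevels(co_g) < 2) co_g <- NULL
    fit <- tryCatch(fit_ll(d$y[in_g], X, co_g), error = function(e) NULL)
    if (is.null(fit)) next
    cf <- summary(fit)$coefficients
    i <- match(sprintf("`%s`", snp_a), rownames(cf))
    if (is.na(i)) i <- match(snp_a, rownames(cf))
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = g, n = n, log_or = cf[i, 1], se = cf[i, 2],
      ci_lower = cf[i, 1] - 1.96 * cf[i, 2],
      ci_upper = cf[i, 1] + 1.96 * cf[i, 2]
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(stratum = integer(), n = integer(),
                                      log_or = numeric(), se = numeric(),
                                      ci_lower = numeric(), ci_upper = numeric())
  rownames(out) <- NULL
  out
}
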