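#' Logistic regression of case status on dosage and covariate terms
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) of phenotype on counted-allele dosages, with
#' optional cohort indicator covariates. Individuals missing any used
#' genotype are excluded. Separation is detected and reported as an error
#' naming the offending term.
#'
#' @param data a [genotype_dataset()].
#' @param snp_terms SNP ids entering as dosage main effects.
#' @param interaction_terms optional list of `c(snp_a, snp_b)` pairs
#'   entering as dosage products.
#' @param cohort_covariate include cohort fixed-effect indicators
#'   (default `TRUE` when more than one cohort is present).
#' @param extra optional numeric matrix of additional covariates (rows
#'   matching individuals).
#' @return A `logistic_fit`: coefficient table (estimate, SE, Wald z and
#'   p), log-likelihood, null log-likelihood and n.
#' @export
fit_logistic <- function(data, snp_terms, interaction_terms = NULL,
                         cohort_covariate = NULL, extra = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (anyDuplicated(snp_terms)) stop("duplicate SNP term")
  if (is.null(cohort_covariate))
    cohort_covariate <- length(unique(data$individuals$cohort)) > 1
  y <- as.integer(data$individuals$phenotype == "case")
  X <- NULL
  used_snps <- snp_terms
  if (length(snp_terms)) X <- dosages(data, snp_terms)
  if (!is.null(interaction_terms)) {
    for (pr in interaction_terms) {
      used_snps <- union(used_snps, pr)
      prod_col <- dosages(data, pr[1]) * dosages(data, pr[2])
      colnames(prod_col) <- paste0(pr[1], ":", pr[2])
      X <- cbind(X, prod_col)
    }
  }
  if (!is.null(extra)) X <- cbind(X, extra)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (any(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    const <- colnames(X)[apply(X, 2, function(col) length(unique(col)) == 1L)]
    stop("constant term(s): ", paste(const, collapse = ", "))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  if (cohort_covariate) {
    df$.cohort <- factor(data$individuals$cohort[keep])
    if (nlevels(df$.cohort) > 1)
      form <- stats::update(form, . ~ . + .cohort)
  }
  if (nrow(df) <= ncol(X) + 1L) stop("more terms than observations")
  fit <- stats::glm(form, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (anyNA(stats::coef(fit)))
    stop("perfectly collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  cf <- summary(fit)$coefficients
  big <- rownames(cf)[abs(cf[, 1]) > 15 & rownames(cf) != "(Intercept)"]
  if (!fit$converged || length(big))
    stop("separation or non-convergence detected for term(s): ",
         paste(if (length(big)) big else "unknown", collapse = ", "))
  null_ll <- -0.5 * fit$null.deviance
  structure(
    list(
      coefficients = data.frame(
        term = gsub("`", "", rownames(cf)), estimate = cf[, 1], se = cf[, 2],
        z = cf[, 3], p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE
      ),
      log_lik = as.numeric(stats::logLik(fit)), null_log_lik = null_ll,
      n = nrow(df), glm = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: n = %d, logLik = %.3f\n", x$n, x$log_lik))
  tab <- x$coefficients
  tab$or <- exp(tab$estimate)
  print(tab, digits = 4)
  invisible(x)
}

#' Extract a named coefficient (log odds) from a logistic fit
#' @param fit a `logistic_fit`.
#' @param term coefficient name.
#' @return Named numeric of length 1.
#' @export
coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("no coefficient named ", term)
  stats::setNames(fit$coefficients$estimate[i], term)
}

#' Mutual conditional association scan
#'
#' For each target SNP, fits the unadjusted single-SNP logistic model and
#' the model conditioned on the dosages of the remaining (conditioning)
#' SNPs, optionally with cohort indicator covariates in both.
#'
#' @param data a [genotype_dataset()].
#' @param target_snps SNPs whose conditional effect is of interest.
#' @param conditioning_sets list (parallel to `target_snps`) of character
#'   vectors of conditioning SNPs; default: all remaining target SNPs
#'   (mutual conditioning).
#' @param cohort_covariate passed to [fit_logistic()].
#' @return `data.frame` with per-SNP unadjusted and conditioned log OR,
#'   OR and p.
#' @export
conditional_scan <- function(data, target_snps, conditioning_sets = NULL,
                             cohort_covariate = NULL) {
  if (is.null(conditioning_sets))
    conditioning_sets <- lapply(target_snps, function(s) setdiff(target_snps, s))
  stopifnot(length(conditioning_sets) == length(target_snps))
  rows <- list()
  for (i in seq_along(target_snps)) {
    s <- target_snps[i]; cond <- conditioning_sets[[i]]
    if (s %in% cond)
      stop("SNP ", s, " cannot condition on itself")
    un <- fit_logistic(data, s, cohort_covariate = cohort_covariate)
    ad <- fit_logistic(data, c(s, cond), cohort_covariate = cohort_covariate)
    iu <- match(s, un$coefficients$term)
    ia <- match(s, ad$coefficients$term)
    rows[[i]] <- data.frame(
      snp_id = s,
      log_or_unadjusted = un$coefficients$estimate[iu],
      or_unadjusted = exp(un$coefficients$estimate[iu]),
      p_unadjusted = un$coefficients$p[iu],
      log_or_conditioned = ad$coefficients$estimate[ia],
      or_conditioned = exp(ad$coefficients$estimate[ia]),
      p_conditioned = ad$coefficients$p[ia],
      conditioning = paste(cond, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
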