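#' Inverse-variance fixed-effects meta-analysis
#'
#' @param log_or per-study log odds ratios.
#' @param se per-study standard errors (all > 0).
#' @return `list(log_or, se, or, p)` for the pooled effect.
#' @export
fixed_effects_meta <- function(log_or, se) {
  stopifnot(length(log_or) == length(se), length(log_or) >= 1)
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  se_p <- sqrt(1 / sum(w))
  z <- pooled / se_p
  list(log_or = pooled, se = se_p, or = exp(pooled),
       p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran's Q and the I-squared heterogeneity index
#'
#' `Q` is the weighted sum of squared deviations of study effects from the
#' fixed-effects pooled estimate; `I2 = max(0, (Q - (k-1))/Q) * 100`
#' expresses the fraction of variability beyond sampling error, on 0-100%.
#'
#' @inheritParams fixed_effects_meta
#' @return `list(q, q_p, i2, k)`.
#' @export
heterogeneity <- function(log_or, se) {
  k <- length(log_or)
  stopifnot(k >= 2, length(se) == k)
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - pooled)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q = q, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE), i2 = i2, k = k)
}

# profile log-likelihood of the random-effects model at a given tau2
# (the mean is profiled out in closed form)
re2_profile_ll <- function(tau2, log_or, se) {
  v <- se^2 + tau2
  mu <- sum(log_or / v) / sum(1 / v)
  sum(stats::dnorm(log_or, mu, sqrt(v), log = TRUE))
}

#' Random-effects meta-analysis (Han-Eskin likelihood-ratio form)
#'
#' Tests the joint null (no mean effect, no between-study variance)
#' against the free random-effects model `beta_i ~ N(mu, se_i^2 + tau2)`
#' by likelihood ratio. `mu` and `tau2` are found by bounded numerical
#' maximisation (profile likelihood in `tau2`), and the p-value uses the
#' 50:50 mixture of chi-square 1-df and 2-df asymptotics for a parameter
#' on the boundary.
#'
#' @inheritParams fixed_effects_meta
#' @return `list(log_or, tau2, or, statistic, p)`.
#' @export
random_effects_meta <- function(log_or, se) {
  k <- length(log_or)
  stopifnot(k >= 2, length(se) == k)
  if (any(se <= 0)) stop("standard errors must be positive")
  ll0 <- sum(stats::dnorm(log_or, 0, se, log = TRUE))
  upper <- 10 * max(se^2) + 10 * stats::var(log_or)
  op <- stats::optimize(re2_profile_ll, c(0, upper), log_or = log_or, se = se,
                        maximum = TRUE, tol = 1e-10)
  tau2 <- op$maximum
  if (re2_profile_ll(0, log_or, se) >= op$objective) tau2 <- 0
  ll1 <- re2_profile_ll(tau2, log_or, se)
  if (!is.finite(ll1)) stop("random-effects likelihood did not converge")
  v <- se^2 + tau2
  mu <- sum(log_or / v) / sum(1 / v)
  s <- max(0, 2 * (ll1 - ll0))
  p <- 0.5 * stats::pchisq(s, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(s, 2, lower.tail = FALSE)
  list(log_or = mu, tau2 = tau2, or = exp(mu), statistic = s, p = p)
}

#' Meta-analysis of per-cohort association results
#'
#' Pools the per-cohort log odds ratios of every SNP under both the
#' fixed-effects and the Han-Eskin random-effects model, with Cochran's Q
#' and I-squared heterogeneity statistics.
#'
#' @param assoc per-cohort results from [cohort_association()].
#' @return `data.frame`, one row per SNP, mirroring the replication-table
#'   layout (OR and p under both models, I2, Q p-value, k cohorts).
#' @export
meta_analysis <- function(assoc) {
  rows <- lapply(split(assoc, assoc$snp_id), function(d) {
    if (nrow(d) < 2)
      stop("pooling requires >= 2 cohorts for SNP ", d$snp_id[1])
    fe <- fixed_effects_meta(d$log_or, d$se)
    re <- random_effects_meta(d$log_or, d$se)
    het <- heterogeneity(d$log_or, d$se)
    data.frame(
      snp_id = d$snp_id[1], k = nrow(d),
      or_fixed = fe$or, p_fixed = fe$p,
      or_random = re$or, p_random = re$p,
      i2 = het$i2, q = het$q, q_p = het$q_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[match(unique(assoc$snp_id), out$snp_id), ]
  rownames(out) <- NULL
  out
}

#' Analytic power of the trend test under a log-additive model
#'
#' Genotype frequencies are Hardy-Weinberg at the population allele
#' frequency; penetrances follow a log-additive model `(1, rr, rr^2)`
#' scaled to the stated disease prevalence; power is the normal
#' approximation to the Cochran-Armitage trend test with additive scores.
#'
#' @param freq population frequency of the tested allele.
#' @param genotype_rr per-allele (genotype relative) risk; values below 1
#'   describe a protective allele.
#' @param n_cases,n_controls planned sample sizes.
#' @param prevalence disease prevalence (default 0.01).
#' @param alpha two-sided significance level (default 0.01).
#' @return Power, in `[alpha, 1]`.
#' @export
power_trend <- function(freq, genotype_rr, n_cases, n_controls,
                        prevalence = 0.01, alpha = 0.01) {
  stopifnot(freq > 0, freq < 1, genotype_rr > 0, prevalence > 0,
            prevalence < 1, alpha > 0, alpha < 1)
  s <- 0:2
  pg <- stats::dbinom(s, 2, freq)
  risk <- genotype_rr^s
  k <- prevalence / sum(pg * risk)
  pen <- k * risk
  q_case <- pg * pen / prevalence
  q_ctl <- pg * (1 - pen) / (1 - prevalence)
  mu1 <- sum(s * q_case); mu0 <- sum(s * q_ctl)
  v1 <- sum(s^2 * q_case) - mu1^2
  v0 <- sum(s^2 * q_ctl) - mu0^2
  n1 <- n_cases; n0 <- n_controls
  pbar <- (n1 * q_case + n0 * q_ctl) / (n1 + n0)
  vbar <- sum(s^2 * pbar) - sum(s * pbar)^2
  se0 <- sqrt(vbar * (1 / n1 + 1 / n0))        # null SE of the mean-score gap
  se1 <- sqrt(v1 / n1 + v0 / n0)               # alternative SE
  delta <- mu1 - mu0
  z_crit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((-z_crit * se0 - delta) / se1) +
    stats::pnorm((delta - z_crit * se0) / se1)
}
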