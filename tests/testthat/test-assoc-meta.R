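test_that("trend test matches its closed form, base-R oracle and permutations", {
  tt <- trend_test(c(30, 20, 10), c(10, 20, 30))
  # independent oracle: chi-square test for trend in proportions
  pt <- suppressWarnings(stats::prop.trend.test(c(30, 20, 10), c(40, 40, 40), score = 0:2))
  expect_equal(tt$statistic, unname(pt$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, pt$p.value, tolerance = 1e-12)

  # permutation oracle on a milder table
  ca <- c(44, 40, 16); co <- c(30, 48, 22)
  tt2 <- trend_test(ca, co)
  g <- rep(0:2, ca + co)
  y <- rep(c(1, 0), c(sum(ca), sum(co)))
  # observed statistic depends on genotypes only through the case row
  set.seed(77)
  perm <- replicate(2e4, {
    yp <- sample(y)
    cap <- c(sum(yp[g == 0]), sum(yp[g == 1]), sum(yp[g == 2]))
    trend_test(cap, c(sum(g == 0), sum(g == 1), sum(g == 2)) - cap)$statistic
  })
  # the statistic is discrete: the chi-square p must fall inside the
  # permutation bracket [P(> obs), P(>= obs)] up to Monte-Carlo error
  p_hi <- mean(perm >= tt2$statistic - 1e-9)
  p_lo <- mean(perm > tt2$statistic + 1e-9)
  mc_err <- 3 * sqrt(p_hi * (1 - p_hi) / 2e4)
  expect_gt(tt2$p_value, p_lo - mc_err)
  expect_lt(tt2$p_value, p_hi + mc_err)

  # identical rows: statistic 0, p 1; case/control swap invariance
  tt3 <- trend_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(tt3$statistic, 0)
  expect_equal(tt3$p_value, 1)
  expect_equal(trend_test(ca, co)$statistic, trend_test(co, ca)$statistic)
  expect_warning(trend_test(c(10, 0, 0), c(20, 0, 0)), "monomorphic")
})

test_that("allelic odds ratios follow Woolf with Haldane correction", {
  o <- allelic_or(c(10, 90), c(20, 80))
  expect_equal(o$or, (10 * 80) / (90 * 20), tolerance = 1e-12)
  expect_equal(allelic_or(c(50, 50), c(50, 50))$or, 1)
  # 0.5 added to every cell iff a zero cell occurs
  oz <- allelic_or(c(0, 100), c(10, 90))
  expect_equal(oz$or, (0.5 * 90.5) / (100.5 * 10.5), tolerance = 1e-12)
  expect_error(allelic_or(c(0, 100), c(0, 90)), "zero cells")

  # Woolf interval close to the profile-likelihood interval (400 chromosomes)
  a <- 30; b <- 170; c_ <- 50; d <- 150
  ll <- function(theta, p0) {
    p1 <- stats::plogis(stats::qlogis(p0) + theta)
    stats::dbinom(a, a + b, p1, log = TRUE) +
      stats::dbinom(c_, c_ + d, p0, log = TRUE)
  }
  prof <- function(theta)
    stats::optimize(function(p0) ll(theta, p0), c(1e-6, 1 - 1e-6),
                    maximum = TRUE)$objective
  th_hat <- log(a * d / (b * c_))
  cut <- prof(th_hat) - stats::qchisq(0.95, 1) / 2
  lo <- stats::uniroot(function(t) prof(t) - cut, c(th_hat - 3, th_hat))$root
  hi <- stats::uniroot(function(t) prof(t) - cut, c(th_hat, th_hat + 3))$root
  o2 <- allelic_or(c(a, b), c(c_, d))
  expect_lt(abs(log(o2$ci[1]) - lo) / abs(lo), 0.1)
  expect_lt(abs(log(o2$ci[2]) - hi) / abs(hi), 0.1)
})

test_that("fixed-effects pooling matches closed forms and metafor", {
  one <- fixed_effects_meta(0.3, 0.1)
  expect_equal(one$log_or, 0.3)
  expect_equal(one$se, 0.1)
  two <- fixed_effects_meta(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(two$log_or, 0.3)
  expect_equal(two$se, 0.1 / sqrt(2))

  b <- c(0.25, -0.05, 0.4); s <- c(0.12, 0.2, 0.3)
  fe <- fixed_effects_meta(b, s)
  w <- 1 / s^2
  expect_equal(fe$log_or, sum(w * b) / sum(w), tolerance = 1e-12)
  het <- heterogeneity(b, s)
  rma <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(fe$log_or, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(fe$p, rma$pval, tolerance = 1e-8)
  expect_equal(het$q, rma$QE, tolerance = 1e-8)
  expect_equal(het$q_p, rma$QEp, tolerance = 1e-8)

  # pooled estimate lies inside the hull; ordering does not matter
  expect_gte(fe$log_or, min(b)); expect_lte(fe$log_or, max(b))
  o <- c(3, 1, 2)
  expect_equal(fixed_effects_meta(b[o], s[o])$log_or, fe$log_or)
  expect_equal(random_effects_meta(b[o], s[o])$p,
               random_effects_meta(b, s)$p, tolerance = 1e-9)
  expect_error(fixed_effects_meta(0.2, 0), "positive")
})

test_that("heterogeneity statistics respect their bounds and bands", {
  expect_equal(heterogeneity(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.1))$q, 0)
  expect_equal(heterogeneity(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.1))$i2, 0)
  # Q below its df truncates I2 at zero
  h <- heterogeneity(c(0.20, 0.21, 0.19), c(0.2, 0.2, 0.2))
  expect_lt(h$q, 2)
  expect_equal(h$i2, 0)
  # a medium-heterogeneity configuration lands in the 50-75% band
  hm <- heterogeneity(c(-0.36, -0.02, -0.25, 0.065, -0.33),
                      c(0.12, 0.12, 0.12, 0.12, 0.12))
  expect_gt(hm$i2, 50)
  expect_lt(hm$i2, 75)
})

test_that("random-effects likelihood maximisation matches a grid oracle", {
  b <- c(-0.60, 0.05, -0.35, 0.30, -0.50, -0.05)
  s <- c(0.15, 0.12, 0.20, 0.14, 0.25, 0.11)
  re <- random_effects_meta(b, s)
  prof <- function(t2) {
    v <- s^2 + t2
    mu <- sum(b / v) / sum(1 / v)
    sum(stats::dnorm(b, mu, sqrt(v), log = TRUE))
  }
  # coarse-to-fine grid search over tau2
  grid <- seq(0, 2, length.out = 4001)
  t2 <- grid[which.max(vapply(grid, prof, 0))]
  for (w in c(1e-3, 1e-5)) {
    grid <- seq(max(0, t2 - w), t2 + w, length.out = 2001)
    t2 <- grid[which.max(vapply(grid, prof, 0))]
  }
  expect_lt(abs(re$tau2 - t2), 1e-6)

  # with homogeneous effects the RE p is within a factor 2 of fixed effects
  bh <- c(0.07, 0.08, 0.075, 0.075); sh <- c(0.1, 0.1, 0.1, 0.1)
  pf <- fixed_effects_meta(bh, sh)$p
  pr <- random_effects_meta(bh, sh)$p
  expect_lt(pr / pf, 2)
  expect_gt(pr / pf, 0.5)
})

test_that("meta_analysis table pools every SNP across cohorts", {
  d <- simulate_case_control(igan_sim_config(300, 300, seed = 12))
  m <- meta_analysis(cohort_association(d))
  expect_equal(nrow(m), 12)
  expect_true(all(m$k == 3))
  expect_true(all(m$i2 >= 0 & m$i2 <= 100))
  expect_true(all(m$q >= 0))
})

test_that("analytic trend-test power matches its limits and simulation", {
  expect_equal(power_trend(0.3, 1, 1000, 1000, alpha = 0.01), 0.01,
               tolerance = 1e-9)
  # replication-cohort scale: a protective OR of 0.7 is essentially certain
  expect_gt(power_trend(0.2, 0.7, 2228, 2561, prevalence = 0.01,
                        alpha = 0.01), 0.99)

  # simulation oracle at a mid-power design
  freq <- 0.3; rr <- 1.3; n1 <- 500; n0 <- 500; alpha <- 0.05
  pg <- stats::dbinom(0:2, 2, freq)
  pen <- 0.05 / sum(pg * rr^(0:2)) * rr^(0:2)
  qca <- pg * pen / sum(pg * pen)
  qco <- pg * (1 - pen) / sum(pg * (1 - pen))
  set.seed(19)
  hits <- replicate(2000, {
    ca <- as.vector(stats::rmultinom(1, n1, qca))
    co <- as.vector(stats::rmultinom(1, n0, qco))
    trend_test(ca, co)$p_value < alpha
  })
  ana <- power_trend(freq, rr, n1, n0, prevalence = 0.05, alpha = alpha)
  expect_lt(abs(ana - mean(hits)), 0.03)
})

test_that("trend test holds its null type-I error", {
  set.seed(23)
  freq <- 0.3
  pg <- stats::dbinom(0:2, 2, freq)
  rej <- replicate(1e4, {
    ca <- as.vector(stats::rmultinom(1, 300, pg))
    co <- as.vector(stats::rmultinom(1, 300, pg))
    trend_test(ca, co)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})
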