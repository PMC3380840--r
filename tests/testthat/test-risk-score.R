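test_that("raw scores follow the weighted-sum arithmetic", {
  model <- igan_model()
  panel <- igan_snp_panel()
  snps7 <- panel[match(model$snp_ids, panel$snp_id), ]
  rownames(snps7) <- NULL
  geno <- matrix(0L, 4, 7, dimnames = list(NULL, model$snp_ids))
  geno[2, c("rs6677604", "rs2412971")] <- 2L   # homozygous at two loci only
  geno[3, ] <- 1L
  geno[4, c("rs9275224")] <- NA
  d <- toy_dataset(geno, snps = snps7,
                   phenotype = c("case", "control", "case", "control"))
  sc <- compute_scores(model, d)
  # missing genotype excludes the individual rather than imputing
  expect_equal(nrow(sc), 3)
  expect_equal(sc$raw[1], 0)
  expect_equal(sc$raw[2], 2 * (-0.49371) + 2 * (-0.28592) + 4 * 0.23171,
               tolerance = 1e-12)
  expect_equal(sc$raw[2], -0.63242, tolerance = 1e-9)
  expect_equal(mean(sc$z), 0, tolerance = 1e-8)
  expect_equal(sd(sc$z), 1, tolerance = 1e-8)
  expect_error(compute_scores(model, subset_dataset(d, snps = 1:5)), "absent")
})

test_that("ranking metrics are affine-invariant and match a pairwise oracle", {
  d <- simulate_case_control(igan_sim_config(250, 250, seed = 71))
  sc <- compute_scores(igan_model(), d)
  perf <- score_performance(sc)

  # affine transform of the raw score: identical z, OR per SD and C
  sc2 <- sc
  sc2$raw <- 3 + 2 * sc$raw
  sc2$z <- (sc2$raw - mean(sc2$raw)) / sd(sc2$raw)
  perf2 <- score_performance(sc2)
  expect_equal(perf2$or_per_sd, perf$or_per_sd, tolerance = 1e-9)
  expect_equal(perf2$c_statistic, perf$c_statistic, tolerance = 1e-12)

  # brute-force concordant-pair C on a 500-individual subset
  y <- sc$phenotype == "case"
  zc <- sc$z[y][1:250]; zn <- sc$z[!y][1:250]
  conc <- 0
  for (i in seq_along(zc)) {
    conc <- conc + sum(zc[i] > zn) + 0.5 * sum(zc[i] == zn)
  }
  sub <- sc[c(which(y)[1:250], which(!y)[1:250]), ]
  class(sub) <- class(sc)
  expect_equal(score_performance(sub)$c_statistic,
               conc / (250 * 250), tolerance = 1e-12)
})

test_that("degenerate performance inputs behave as specified", {
  d <- simulate_case_control(igan_sim_config(2500, 2500, seed = 72,
                                             cohorts = data.frame(
                                               label = "c1",
                                               ethnicity = "European")))
  sc <- compute_scores(igan_model(), d)
  # score independent of phenotype: permute labels, expect null metrics
  set.seed(73)
  sc_null <- sc
  sc_null$phenotype <- sample(sc$phenotype)
  p0 <- score_performance(sc_null)
  expect_lt(p0$r2_nagelkerke, 0.002)
  expect_lt(abs(p0$c_statistic - 0.5), 0.03)
  # a perfectly separating score has C = 1
  sc_sep <- sc
  sc_sep$z <- ifelse(sc$phenotype == "case", sc$z + 100, sc$z - 100)
  expect_equal(suppressWarnings(score_performance(sc_sep))$c_statistic, 1)
})

test_that("Nagelkerke R2 is monotone over nested models", {
  d <- simulate_case_control(igan_sim_config(700, 700, seed = 74))
  nag <- function(fit) {
    n <- fit$n
    (1 - exp(2 * (fit$null_log_lik - fit$log_lik) / n)) /
      (1 - exp(2 * fit$null_log_lik / n))
  }
  f_small <- fit_logistic(d, c("rs6677604", "rs2412971"),
                          cohort_covariate = FALSE)
  f_big <- fit_logistic(d, igan_model()$snp_ids, cohort_covariate = FALSE)
  expect_gte(nag(f_big), nag(f_small))
  expect_gte(nag(f_small), 0)
})

test_that("stepwise selection honours BIC descent, hierarchy and nulls", {
  d <- simulate_case_control(igan_sim_config(1200, 1200, seed = 75))
  model <- stepwise_bic(d, igan_snp_panel()$snp_id,
                        pair_candidates = utils::combn(igan_model()$snp_ids,
                                                       2, simplify = FALSE))
  trace <- attr(model, "trace")
  expect_true(all(diff(trace$bic) < 0))
  prs <- model$terms[!is.na(model$terms$snp_b), ]
  mains <- model$terms$snp_a[is.na(model$terms$snp_b)]
  expect_true(all(c(prs$snp_a, prs$snp_b) %in% mains))

  # pure-noise candidates at informative n select nothing
  cfg <- sim_config(
    snps = toy_snps(8),
    cohorts = data.frame(label = "c1", ethnicity = "European",
                         n_cases = 2500, n_controls = 2500),
    control_freqs = matrix(seq(0.15, 0.5, length.out = 8), 1, 8),
    betas = c(snp01 = 0), prevalence = 0.05, seed = 76
  )
  d0 <- simulate_case_control(cfg)
  m0 <- stepwise_bic(d0, cfg$snps$snp_id)
  expect_equal(nrow(m0$terms), 0)
})

test_that("protective-allele counts are tabulated, binned and compared", {
  d <- simulate_case_control(igan_sim_config(700, 700, seed = 77))
  res <- allele_count_distribution(d, igan_model())
  expect_equal(colnames(res$distributions), as.character(0:14))
  expect_true(all(res$counts$count >= 0 & res$counts$count <= 14))
  # East Asian vs African-American protective-allele distributions differ
  expect_lt(res$p_values["East Asian", "African American"], 1e-4)

  # identical groups give a null statistic
  x <- c(5, 30, 80, 120, 80, 30, 5)
  bc <- binned_chisq(x, x)
  expect_equal(bc$statistic, 0)
  expect_equal(bc$p, 1)

  # a sparse tail (expected counts below 5) is merged inward
  y <- c(1, 40, 90, 110, 85, 25, 2)
  bc2 <- binned_chisq(x, y)
  expect_lt(bc2$bins, length(x))
})
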