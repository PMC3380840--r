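# shared fixture builders; everything is generated in code

toy_snps <- function(m = 2) {
  snp_info(
    snp_id = sprintf("snp%02d", seq_len(m)),
    chromosome = rep("1", m), position_kb = seq_len(m) * 10,
    counted_allele = rep("A", m), other_allele = rep("G", m)
  )
}

# dataset built directly from a dosage matrix (one cohort unless given)
toy_dataset <- function(geno, phenotype = NULL, cohort = "c1",
                        ethnicity = "European", snps = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(snps)) snps <- toy_snps(ncol(geno))
  if (is.null(phenotype))
    phenotype <- rep(c("case", "control"), length.out = n)
  genotype_dataset(
    geno, snps,
    data.frame(individual_id = sprintf("i%04d", seq_len(n)),
               cohort = rep(cohort, length.out = n),
               ethnicity = rep(ethnicity, length.out = n),
               phenotype = phenotype, stringsAsFactors = FALSE)
  )
}

# random dataset with missingness for round-trip tests
random_dataset <- function(n = 25, m = 4, missing_rate = 0.1, seed = 42) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  geno[runif(n * m) < missing_rate] <- NA_integer_
  snps <- snp_info(
    snp_id = sprintf("rs%d", seq_len(m) * 101),
    chromosome = sample(c("1", "6", "22"), m, replace = TRUE),
    position_kb = round(runif(m, 1, 1e5), 3),
    counted_allele = rep(c("A", "C"), length.out = m),
    other_allele = rep(c("G", "T"), length.out = m)
  )
  genotype_dataset(
    geno, snps,
    data.frame(individual_id = sprintf("id%03d", seq_len(n)),
               cohort = rep(c("coA", "coB"), length.out = n),
               ethnicity = rep("European", n),
               phenotype = sample(c("case", "control"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  )
}

# single-SNP case-control simulation config
single_snp_config <- function(beta, freq = 0.3, n_cases = 500,
                              n_controls = 500, prevalence = 0.05,
                              seed = 1) {
  sim_config(
    snps = toy_snps(1),
    cohorts = data.frame(label = "c1", ethnicity = "European",
                         n_cases = n_cases, n_controls = n_controls,
                         stringsAsFactors = FALSE),
    control_freqs = matrix(freq, 1, 1),
    betas = c(snp01 = beta), prevalence = prevalence, seed = seed
  )
}
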