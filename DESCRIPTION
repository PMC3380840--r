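Package: igarisk
Title: Genetic Association, Risk Scores, and Geospatial Epidemiology for
    IgA Nephropathy SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for small replication panels of IgA nephropathy
    (IgAN) susceptibility SNPs: genotype input/output and quality control,
    per-cohort Cochran-Armitage association with per-allele odds ratios,
    fixed-effects and Han-Eskin random-effects meta-analysis with Cochran's Q
    and I2 heterogeneity, conditional logistic analysis and EM haplotype
    phasing with reference-relative haplotype odds ratios, exhaustive
    first-order SNP-SNP interaction screening (multiplicative 1-df and
    Cordell-Clayton 4-df tests), a BIC-selected weighted genetic risk score
    with Nagelkerke R2 and C-statistic, and geospatial modelling of
    population-median genetic risk (polynomial trend surfaces, ordinary
    kriging with exponential covariance) correlated with end-stage renal
    disease registry metrics. A seeded synthetic-data generator emulates the
    multi-cohort case-control design and geographically clined allele
    frequencies so the full chain runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    spatial
Config/testthat/edition: 3
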