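# igarisk

Genetic association, weighted risk scores, and geospatial epidemiology
for IgA nephropathy (IgAN) SNP panels.

IgAN, the most common primary glomerulonephritis worldwide, shows a
marked geographic gradient — frequent in East Asia, intermediate in
Europe, rare in populations of African ancestry. A small panel of
replicated susceptibility loci (a *CFHR3/R1* deletion tag on 1q32, three
independent MHC intervals on 6p21, and the *HORMAD2* locus on 22q12)
carries enough signal that a weighted allele score tracks both
individual disease risk and population-level disease prevalence.
`igarisk` implements the full analysis chain for such panels:

* **I/O and QC** — PED/MAP and TSV genotype dialects with counted-allele
  dosage storage; per-cohort filters (MAF > 1%, missingness < 5%, exact
  Hardy–Weinberg p > 0.01 in controls, ≤ 2 missing genotypes per
  individual).
* **Association and meta-analysis** — 1-df Cochran–Armitage trend test,
  per-allele Woolf odds ratios, inverse-variance fixed effects, a
  random-effects likelihood-ratio model
  (β<sub>i</sub> ~ N(μ, se<sub>i</sub>² + τ²), p from the 50:50
  χ²<sub>1</sub>/χ²<sub>2</sub> boundary mixture), Cochran's Q and I²,
  and analytic trend-test power.
* **Conditional and haplotype analysis** — mutual conditional logistic
  scans; EM haplotype phasing (≤ 8 SNPs, seeded multi-start) with
  reference-relative haplotype odds ratios
  OR<sub>h</sub> = (f<sup>case</sup><sub>h</sub>/f<sup>case</sup><sub>ref</sub>) /
  (f<sup>ctl</sup><sub>h</sub>/f<sup>ctl</sup><sub>ref</sub>)
  and a global χ² over common (> 1%) haplotypes.
* **Interaction screening** — all pairwise 1-df multiplicative LRTs on
  dosage products at the Bonferroni threshold 0.05/21, plus the 4-df
  genotypic test with Cordell–Clayton coding (x<sub>a</sub> = −1, 0, 1;
  x<sub>d</sub> = −0.5, 0.5, −0.5) and per-stratum allelic effects.
* **Risk score** — bidirectional BIC stepwise selection with forced
  cohort covariates and term hierarchy; raw score
  S = Σ β<sub>j</sub> g<sub>j</sub> + β<sub>jk</sub> g<sub>j</sub> g<sub>k</sub>
  over counted-allele dosages, z-standardised; per-SD odds ratio,
  Nagelkerke R², rank-based C-statistic; protective-allele-count
  distribution comparisons with tail binning.
* **Geospatial epidemiology** — population-median standardised scores,
  degree-3 polynomial trend surfaces, ordinary kriging with exponential
  covariance C(h) = sill·e<sup>−h/range</sup> over great-circle
  distances, longitude/latitude correlations, and ESRD registry metrics
  (incidence/prevalence per million, % of ESRD, % of GN-ESRD) regressed
  on latitude.

A seeded synthetic-data module (`sim_config()`,
`simulate_case_control()`, `simulate_geographic_panel()`) reproduces the
multi-cohort case-control design — Hardy–Weinberg genotypes at
cohort-specific frequencies, an HLA LD block with published haplotype
frequencies, a log-additive logistic disease model with exact
prevalence-calibrated intercepts, rejection-sampled case/control
ascertainment — so the entire chain runs without any external data.

## Worked example

```r
library(igarisk)

## a replication-style study: 3 cohorts, ~20,000 subjects, 1% prevalence
cfg <- igan_sim_config(3333, 3333, seed = 7)
d   <- simulate_case_control(cfg)
qc  <- qc_filter(d)

## meta-analysis across cohorts
meta <- meta_analysis(cohort_association(qc$data))
head(meta[, c("snp_id", "or_fixed", "p_fixed", "or_random", "i2")], 3)
#>      snp_id or_fixed   p_fixed or_random    i2
#> 1 rs3766404   0.9515 5.044e-02    0.9516 42.05
#> 2 rs6677604   0.7392 7.072e-30    0.7163 83.22
#> 3 rs9275224   0.7535 5.579e-42    0.7535 45.60

## conditional dissection of the HLA interval: the rs2856717 minor
## allele is protective marginally but a risk allele once rs9275596
## is adjusted for
cs <- conditional_scan(d, c("rs9275224", "rs2856717", "rs9275424",
                            "rs9275596"))
cs[cs$snp_id == "rs2856717", c("or_unadjusted", "or_conditioned")]
#>   or_unadjusted or_conditioned
#> 2     0.7912616       1.483244

## the weighted seven-SNP risk score with its interaction term
scores <- compute_scores(igan_model(), d)
perf   <- score_performance(scores)
c(r2 = perf$r2_nagelkerke, C = perf$c_statistic, or_sd = perf$or_per_sd)
#>         r2          C      or_sd
#> 0.04594443 0.60642405 1.46764160
```

The per-SD odds ratio ≈ 1.46 means one standard deviation of the score
multiplies the odds of disease by about 1.5; the score explains ≈ 4.6%
of disease variance (Nagelkerke) and discriminates cases from controls
with C ≈ 0.61 — the magnitudes expected for a seven-locus panel of
modest-effect common variants.

```r
## genetic risk across a simulated 50-population panel with an eastward
## decline in protective-allele frequencies
cl <- setNames(rep(-0.003, 7), igan_model()$snp_ids)
cl["rs2856717"] <- 0.0015
panel <- simulate_geographic_panel(geo_sim_config(50, 25, seed = 3,
                                                  cline_lon = cl))
pm <- population_medians(compute_scores(igan_model(), panel$data),
                         panel$populations)
geographic_correlation(pm, "longitude")$r   # median risk rises eastward
#> [1] 0.9497861
surface <- fit_trend_surface(pm, degree = 3)
kriged  <- krige(pm)                        # exponential-covariance kriging

## registry epidemiology on the bundled synthetic European table
era <- read_prevalence_table(system.file(
  "extdata", "era_edta_igan_esrd_synthetic.csv", package = "igarisk"))
lr <- latitude_regression(epi_metrics(era))
lr[lr$metric == "incidence_pmp", c("r", "p")]
#>       r       p
#> 1 0.5398 0.05692
```

The bundled registry tables are *synthetic* stand-ins (see the
vignette): they emulate the magnitude and latitude gradient of European
and US renal-registry data, including the ~15-fold Asian-American :
African-American difference in the share of ESRD attributable to IgAN.

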