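---
title: "Genetic association, risk scores and geospatial epidemiology of IgA nephropathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic association, risk scores and geospatial epidemiology of IgA nephropathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igarisk)
```

## The scientific problem

IgA nephropathy (IgAN) is the most common primary glomerulonephritis
worldwide and shows a striking geographic gradient: common in East Asia,
intermediate in Europe, rare in populations of African ancestry. A small
panel of replicated susceptibility SNPs — a complement-factor-H-region
deletion tag on 1q32, three independent MHC intervals on 6p21, and the
HORMAD2 locus on 22q12 — carries enough signal that a weighted allele
score tracks both individual disease risk and population-level disease
prevalence. `igarisk` implements that analysis chain end to end on desk
scale: per-cohort association and meta-analysis, conditional and
haplotype dissection of the MHC signal, an exhaustive pairwise
interaction screen, a BIC-selected weighted risk score with performance
metrics, and geospatial modelling of population-median genetic risk
against renal-registry prevalence metrics.

## Data model

Genotypes are stored as counted-allele dosages (0/1/2, `NA` for missing)
with the counted allele fixed per SNP to the reported minor/tested
allele, so that every log odds ratio in the package is per counted
allele and orientation bookkeeping is internal
(`flip_counted_allele()` maps dosage d to 2 - d and is involutive).
Text interchange is deliberately minimal: whitespace-delimited PED/MAP
(with the allele pair declared on the MAP side fixing orientation) and a
TSV dosage dialect, plus CSV for population coordinates and registry
counts.

## The synthetic study design

No individual-level genotypes are distributed with the package. Instead
the generator in `sim_config()` / `simulate_case_control()` reproduces
the *design* of a multi-cohort replication study:

* genotypes are drawn from Hardy–Weinberg proportions at cohort-specific
  population allele frequencies, or from stated haplotype frequencies
  inside LD blocks;
* disease status follows a log-additive logistic model; the intercept is
  calibrated per cohort by exact enumeration of the genotype
  distribution and root finding, so the marginal disease probability
  equals the stated prevalence (default 1%, the standard assumption for
  IgAN power calculations);
* cases and controls are collected by rejection sampling from the
  population stream, which gives exact case/control counts and mirrors
  how rare-disease case-control studies ascertain subjects. A bounded
  draw cap turns an unattainable request into an explicit error.

`igan_sim_config()` wires in the study conditions used throughout the
tests: the seven-SNP reference model with its single dosage-product
interaction (`igan_model()`, coefficients from the combined-cohort
stepwise fit), a four-SNP HLA LD block whose haplotype frequencies are
the published combined-cohort estimates, and a 1% prevalence. Because
published haplotype tables only list haplotypes above 1% frequency, the
block assigns the remaining 0.9% to two rare recombinant haplotypes;
without them some two-SNP genotype cells would be structurally empty,
which real panels do not show. Per-ethnicity allele frequencies outside
the block are illustrative presets (`igan_frequency_presets()`)
reflecting the qualitative pattern that protective alleles are most
frequent in African-ancestry and least frequent in East-Asian
populations; the true per-cohort frequencies were not published and the
presets are editable inputs, not estimates.

What the generator does *not* emulate: realistic genome-wide LD,
admixture, genotyping batch artefacts, or cohort-specific ascertainment
quirks. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
failure mode of real data.

## Association and meta-analysis

Quality control follows the replication thresholds, applied within each
cohort and intersected: minor allele frequency above 1%, per-SNP
missingness below 5%, exact Hardy–Weinberg p above 0.01 in controls, and
at most 2 missing genotypes per individual. The HWE test is the exact
enumeration test rather than the chi-square approximation because
replication cohorts can be small (the African-American cohort in the
motivating study had under 100 subjects).

Per-cohort association uses the 1-df Cochran–Armitage trend test with
additive scores and the Woolf per-allele odds ratio (Haldane 0.5
correction only when a zero cell occurs). Cohorts are pooled by
inverse-variance fixed effects and by a random-effects likelihood-ratio
model in which study effects are normal with variance `se^2 + tau2`:
the test of the joint null (no mean effect, no heterogeneity) is
referred to the 50:50 mixture of 1- and 2-df chi-squares, the standard
boundary asymptotics. This mixture is used instead of tabulated
small-sample corrections; at eight studies it runs slightly
conservative (empirical size about 0.03–0.035 at nominal 0.05 in the
package's own null simulations), which we accept for determinism and
transparency. Cochran's Q and I² quantify heterogeneity; stratified
recruitment sites are treated as separate meta-analysis units, the
conservative choice when within-country heterogeneity cannot be
excluded. Analytic power for the trend test (`power_trend()`) uses the
normal approximation with null and alternative variances computed from
the penetrance-weighted genotype distributions.

## Conditional, haplotype and interaction analyses

`conditional_scan()` refits each target SNP with the remaining SNPs'
dosages as covariates (optionally with cohort indicators). On data
simulated under the default HLA block this reproduces the qualitative
signature that motivates haplotype dissection: the minor allele of
rs2856717 is protective marginally but becomes a risk allele once
rs9275596 is adjusted for, because the protective ATAC and risk ATAT
haplotypes differ only at rs9275596.

`em_phase()` estimates haplotype frequencies for up to 8 SNPs by EM over
the enumerated diplotype expansions. EM for haplotype frequencies is
multimodal in principle, so the run starts from the
product-of-allele-frequency point plus ten random restarts (seeded by
the caller) and keeps the best likelihood; the log-likelihood is
monotone within each run and the suite checks agreement with an
exhaustive simplex maximisation on small instances. Case and control
frequencies are estimated by separate EM runs; `haplotype_association()`
then computes odds ratios as frequency ratios against the most common
haplotype on expected haplotype counts — the arithmetic that reproduces
a published haplotype table directly from its printed frequencies — and
a global chi-square over common (frequency > 1%) haplotypes with
`n_common - 1` df. A dosage-logistic haplotype model would be an
alternative estimator; the frequency-ratio form was chosen because it is
the one recomputable from published group frequencies (the residual
discrepancy of about 0.01 for one haplotype reflects frequency rounding,
and the package tolerances account for it).

The interaction screen tests all pairs of score SNPs with the 1-df
multiplicative likelihood-ratio test on dosage products, cohort
indicators forced into both nested models, at the Bonferroni threshold
0.05/21 for seven SNPs. The 4-df genotypic test uses the
Cordell–Clayton coding (allelic -1/0/1 and dominance -0.5/0.5/-0.5)
with all four cross-products; it is invariant to allele relabelling and
serves as the follow-up test, matching the two-stage practice of
screening multiplicatively and confirming genotypically. Individuals
missing either SNP of a pair are excluded pairwise to maximise per-pair
sample size. `stratum_effects()` emits the per-genotype-class allelic
effects (minimum stratum size 10) that visualise an interaction
reversal.

## The risk score

`stepwise_bic()` is a bidirectional greedy search over main-effect and
dosage-product candidates minimising `BIC = -2 logLik + p log(n)` with
`n` the number of fitted individuals. Cohort indicators are forced;
hierarchy is enforced (a product term may only enter while both mains
are present and protects its mains from removal) because the final
model's interaction retains both mains. Candidates are compared on the
complete-case subset so every BIC refers to the same data.

`compute_scores()` applies signed coefficients to counted-allele
dosages — protective terms carry negative betas, risk terms positive
ones — and excludes (never imputes) individuals missing any scored
genotype, matching the all-loci-complete scoring rule. Standardisation
is a z-transform over all scored individuals by default; a
controls-only reference is available for settings that need a frozen
healthy-population scale. Performance metrics are the per-SD odds ratio
with Wald test, Nagelkerke's pseudo R², and the C-statistic by the
rank (Mann–Whitney) formulation with tie correction.
`allele_count_distribution()` compares protective-allele-count
distributions between groups with a chi-square after merging
distribution tails until every expected count exceeds 5.

## Geospatial modelling and registry epidemiology

Population-level genetic risk is summarised as the median standardised
score of fully scored members (`population_medians()`). Two surfaces
are available: an ordinary-least-squares polynomial trend surface of
total degree 3 (10 monomial terms; coordinates are centred and scaled
internally purely for conditioning, predictions are returned in
original units) and ordinary kriging with exponential covariance
`C(h) = sill exp(-h/range)` plus an optional nugget. Kriging distances
are great-circle kilometres (haversine) rather than Euclidean degrees
— at continental scale degree-space distances distort east-west
separation badly at high latitude. Covariance parameters default to a
weighted-least-squares fit of the empirical semivariogram; because a
trend-dominated semivariogram does not plateau, the sill and range are
box-constrained to the data scale (range at most the maximum observed
pair distance), and a relative diagonal jitter of 1e-8 keeps the dual
kriging system well-posed. With zero nugget the predictor interpolates
training points (to that jitter), and far beyond the range it reverts
to the training mean.

"Eastward distance from the prime meridian" is operationalised as
signed longitude, the simplest reading consistent with a monotone
east-west gradient. Registry analysis computes the three standard
prevalence definitions — IgAN-ESRD per million population, percent of
all ESRD, percent of glomerulonephritis ESRD — plus incidence PMP, and
regresses each on average region latitude (Pearson, two-sided t).
The bundled registry tables are synthetic stand-ins (their filenames
say so): country rows emulate the magnitude and latitude gradient of
European renal-registry data with country-level scatter from biopsy
practice, and the US table emulates the documented ethnic
fold-differences. Centroid latitudes are used; a population-weighted
"average latitude" would shift coordinates by a degree or two, which is
why latitude correlations carry a tolerance in the package's checks.

## Numerical choices and problem sizes

* Logistic fits use IRLS (`stats::glm`) tightened to epsilon 1e-12;
  separation is reported as an error naming the diverging term, and
  aliased columns as a collinearity error.
* EM stops at log-likelihood improvement below 1e-8 or 1,000
  iterations; frequencies are renormalised at the end and sum to one
  within 1e-10.
* The random-effects profile likelihood is maximised over `tau2` by
  Brent search with the mean profiled out in closed form; ties between
  the boundary and interior are resolved toward `tau2 = 0`.
* The intercept calibration root-find runs to 1e-12 on the prevalence
  scale.
* Test and validation problem sizes were chosen to make sampling error
  small relative to the tested tolerance while keeping the default
  suite desk-scale: parameter-recovery and selection-recovery runs use
  10 seeded replicates of about 20,000 individuals; type-I-error checks
  use 500–1,000 null replicates (4,000 for the random-effects test,
  whose size is the quantity of interest); the EM-versus-oracle sweep
  uses instances of up to 3 SNPs and 30 individuals where exhaustive
  maximisation is dependable.

## Known limitations

* The generator's independent-SNP backbone understates LD; only the
  HLA block is haplotype-structured.
* Haplotype odds ratios are frequency-ratio estimates, not
  cohort-adjusted regression estimates; with strong confounding by
  cohort the two can diverge.
* Kriging assumes second-order stationarity that a clined risk surface
  violates; the trend surface (or kriging residuals of it) is the
  appropriate first summary, and the package keeps the two models
  separate rather than composing universal kriging.
* Registry fixtures are synthetic; conclusions about real registries
  require the real tables, which the reader must obtain from the
  registries themselves.
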