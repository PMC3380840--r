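#' The replicated IgAN susceptibility SNP panel
#'
#' Metadata for the 12 SNPs genotyped across the five replicated IgAN
#' susceptibility loci (CFHR3/R1 on 1q32, three MHC intervals on 6p21, and
#' HORMAD2 on 22q12). The counted allele is the reported minor/tested
#' allele; where the complementary allele is not part of the published
#' haplotype alphabet a placeholder base is used (orientation bookkeeping
#' only, it never affects dosages).
#'
#' @return A [snp_info()] table of 12 SNPs.
#' @export
igan_snp_panel <- function() {
  snp_info(
    snp_id = c("rs3766404", "rs6677604", "rs9275224", "rs2856717",
               "rs9275424", "rs9275596", "rs9357155", "rs2071543",
               "rs1883414", "rs3129269", "rs2412971", "rs2412973"),
    chromosome = c("1", "1", "6", "6", "6", "6", "6", "6", "6", "6", "22", "22"),
    position_kb = c(194918, 194953, 32768, 32778, 32779, 32789, 32917,
                    32919, 33194, 33205, 28824, 28859),
    counted_allele = c("C", "A", "A", "T", "G", "C", "A", "A", "T", "T", "A", "A"),
    other_allele  = c("T", "G", "G", "C", "A", "T", "G", "C", "G", "C", "G", "G")
  )
}

#' Reference seven-SNP IgAN risk model
#'
#' The combined-cohort predictive model retained by BIC-stepwise selection:
#' seven SNPs with independent effects plus one dosage-product interaction
#' between the CFHR3/R1 tag (rs6677604) and the HORMAD2 tag (rs2412971).
#' Coefficients are log odds ratios per counted allele and are the weights
#' of the genetic risk score.
#'
#' @return A [risk_score_model()].
#' @export
igan_model <- function() {
  terms <- data.frame(
    snp_a = c("rs6677604", "rs9275224", "rs2856717", "rs9275596",
              "rs9357155", "rs1883414", "rs2412971", "rs6677604"),
    snp_b = c(NA, NA, NA, NA, NA, NA, NA, "rs2412971"),
    beta = c(-0.49371, -0.31307, 0.42265, -0.51157,
             -0.28621, -0.18050, -0.28592, 0.23171),
    stringsAsFactors = FALSE
  )
  risk_score_model(terms)
}

#' Published odds-ratio column of the reference model
#'
#' The per-term odds ratios as printed alongside the reference model
#' coefficients (two decimals), used for consistency checks.
#'
#' @return Named numeric vector of odds ratios.
#' @export
igan_model_printed_or <- function() {
  c("rs6677604" = 0.61, "rs9275224" = 0.73, "rs2856717" = 1.53,
    "rs9275596" = 0.60, "rs9357155" = 0.75, "rs1883414" = 0.83,
    "rs2412971" = 0.75, "rs6677604:rs2412971" = 1.26)
}

#' HLA-DQB1/DRB1 four-SNP haplotype frequencies
#'
#' Group-wise frequencies of the five common haplotypes over rs9275224,
#' rs2856717, rs9275424, rs9275596 estimated in the combined cohort
#' (5,372 cases / 5,383 controls). GCAT is the most common haplotype and
#' the odds-ratio reference.
#'
#' @return A `data.frame` with columns `haplotype`, `freq_overall`,
#'   `freq_cases`, `freq_controls`; group sizes are stored in attributes
#'   `n_cases` and `n_controls`.
#' @export
igan_hla_haplotypes <- function() {
  out <- data.frame(
    haplotype = c("GCAT", "ATAC", "ACAT", "ATAT", "GCGT"),
    freq_overall = c(0.352, 0.213, 0.130, 0.050, 0.246),
    freq_cases = c(0.365, 0.180, 0.119, 0.058, 0.270),
    freq_controls = c(0.338, 0.245, 0.141, 0.043, 0.222),
    stringsAsFactors = FALSE
  )
  attr(out, "n_cases") <- 5372L
  attr(out, "n_controls") <- 5383L
  out
}
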