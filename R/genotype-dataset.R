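#' SNP panel description
#'
#' Builds the per-SNP metadata table used throughout the package. Dosages are
#' always stored for the *counted* allele, i.e. the minor/tested allele whose
#' per-allele odds ratio is reported.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chromosome chromosome labels (character).
#' @param position_kb physical position in kilobases (non-negative).
#' @param counted_allele single-character allele whose copies are counted.
#' @param other_allele the complementary allele label.
#' @return A `data.frame` with one row per SNP.
#' @export
snp_info <- function(snp_id, chromosome, position_kb, counted_allele, other_allele) {
  snp_id <- as.character(snp_id)
  counted_allele <- as.character(counted_allele)
  other_allele <- as.character(other_allele)
  if (anyDuplicated(snp_id)) stop("duplicate snp_id")
  if (any(nchar(counted_allele) != 1L) || any(nchar(other_allele) != 1L))
    stop("alleles must be single characters")
  if (any(counted_allele == other_allele))
    stop("counted_allele must differ from other_allele")
  if (any(position_kb < 0)) stop("position_kb must be >= 0")
  data.frame(
    snp_id = snp_id, chromosome = as.character(chromosome),
    position_kb = as.numeric(position_kb),
    counted_allele = counted_allele, other_allele = other_allele,
    stringsAsFactors = FALSE
  )
}

#' Case-control genotype dataset
#'
#' Container for a panel of biallelic SNPs typed on case-control cohorts.
#' Genotypes are counted-allele dosages in `{0, 1, 2, NA}`.
#'
#' @param genotypes integer matrix, individuals x SNPs; values 0/1/2/`NA`.
#' @param snps SNP table as returned by [snp_info()]; row order must match
#'   the genotype columns.
#' @param individuals `data.frame` with columns `individual_id`, `cohort`,
#'   `ethnicity`, `phenotype` (`"case"` or `"control"`), rows matching the
#'   genotype rows.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, snps, individuals) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(individuals))
    stop("genotype rows do not match individuals")
  if (ncol(genotypes) != nrow(snps))
    stop("genotype columns do not match snps")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  need <- c("individual_id", "cohort", "ethnicity", "phenotype")
  if (!all(need %in% names(individuals)))
    stop("individuals needs columns: ", paste(need, collapse = ", "))
  individuals <- as.data.frame(individuals)[, need]
  individuals$individual_id <- as.character(individuals$individual_id)
  if (anyDuplicated(individuals$individual_id)) stop("duplicate individual_id")
  if (!all(individuals$phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  dimnames(genotypes) <- list(individuals$individual_id, snps$snp_id)
  structure(
    list(genotypes = genotypes, snps = snps, individuals = individuals),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ph <- table(x$individuals$phenotype)
  cat(sprintf(
    "genotype_dataset: %d individuals (%d cases / %d controls), %d SNPs, %d cohorts\n",
    nrow(x$genotypes),
    if ("case" %in% names(ph)) ph[["case"]] else 0L,
    if ("control" %in% names(ph)) ph[["control"]] else 0L,
    ncol(x$genotypes), length(unique(x$individuals$cohort))
  ))
  invisible(x)
}

#' Extract dosage columns
#'
#' @param data a [genotype_dataset()].
#' @param snp_ids SNP identifiers to extract (default all).
#' @return Integer matrix of counted-allele dosages.
#' @export
dosages <- function(data, snp_ids = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(snp_ids)) return(data$genotypes)
  missing_ids <- setdiff(snp_ids, colnames(data$genotypes))
  if (length(missing_ids))
    stop("SNP(s) not in dataset: ", paste(missing_ids, collapse = ", "))
  data$genotypes[, snp_ids, drop = FALSE]
}

#' Flip the counted allele of a SNP
#'
#' Swaps counted/other allele labels and maps every non-missing dosage
#' `d -> 2 - d`. Applying the flip twice restores the original dataset.
#'
#' @param data a [genotype_dataset()].
#' @param snp_ids SNPs to flip.
#' @return The modified dataset.
#' @export
flip_counted_allele <- function(data, snp_ids) {
  stopifnot(inherits(data, "genotype_dataset"))
  idx <- match(snp_ids, data$snps$snp_id)
  if (anyNA(idx)) stop("unknown SNP in snp_ids")
  tmp <- data$snps$counted_allele[idx]
  data$snps$counted_allele[idx] <- data$snps$other_allele[idx]
  data$snps$other_allele[idx] <- tmp
  data$genotypes[, idx] <- 2L - data$genotypes[, idx]
  data
}

#' Subset a genotype dataset
#'
#' @param data a [genotype_dataset()].
#' @param individuals logical/integer/character index over individuals.
#' @param snps logical/integer/character index over SNPs.
#' @return The subsetted dataset.
#' @export
subset_dataset <- function(data, individuals = NULL, snps = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (!is.null(individuals)) {
    if (is.character(individuals))
      individuals <- match(individuals, data$individuals$individual_id)
    data$genotypes <- data$genotypes[individuals, , drop = FALSE]
    data$individuals <- data$individuals[individuals, , drop = FALSE]
    rownames(data$individuals) <- NULL
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, data$snps$snp_id)
    data$genotypes <- data$genotypes[, snps, drop = FALSE]
    data$snps <- data$snps[snps, , drop = FALSE]
    rownames(data$snps) <- NULL
  }
  data
}
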