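#' Read genotypes from PED/MAP or TSV files
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`ped_map`}{whitespace-delimited `<prefix>.ped` /
#'     `<prefix>.map`. The PED file carries six leading columns
#'     (family/cohort, individual id, father, mother, sex, phenotype with
#'     1 = control, 2 = case) followed by two allele columns per SNP;
#'     `"0"` is the missing-allele code. The MAP file carries
#'     `chromosome, snp_id, cM, position_bp, counted_allele, other_allele`;
#'     the trailing allele pair fixes the counted-allele orientation.
#'     The family column is used as the cohort label.}
#'   \item{`tsv`}{`<prefix>.tsv` with columns `individual_id, cohort,
#'     ethnicity, phenotype` followed by one dosage column per SNP, plus a
#'     companion `<prefix>.snps.tsv` with the [snp_info()] columns.}
#' }
#'
#' @param prefix file path without extension.
#' @param dialect `"ped_map"` or `"tsv"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(prefix, dialect = c("ped_map", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") read_ped_map(prefix) else read_geno_tsv(prefix)
}

read_ped_map <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path)) if (!file.exists(p)) stop("file not found: ", p)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- lapply(seq_along(map_lines), function(i) {
    f <- strsplit(trimws(map_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L)
      stop(sprintf("malformed MAP line %d: expected 6 fields, got %d", i, length(f)))
    f
  })
  map <- do.call(rbind, map)
  snps <- snp_info(
    snp_id = map[, 2], chromosome = map[, 1],
    position_kb = as.numeric(map[, 4]) / 1000,
    counted_allele = map[, 5], other_allele = map[, 6]
  )
  m <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  geno <- matrix(NA_integer_, n, m)
  ind <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf("malformed PED line %d: expected %d fields, got %d",
                   i, 6L + 2L * m, length(f)))
    ph <- f[6]
    if (!ph %in% c("1", "2"))
      stop(sprintf("malformed PED line %d: phenotype must be 1 or 2", i))
    ind[[i]] <- data.frame(
      individual_id = f[2], cohort = f[1], ethnicity = NA_character_,
      phenotype = if (ph == "2") "case" else "control",
      stringsAsFactors = FALSE
    )
    a1 <- f[seq(7L, by = 2L, length.out = m)]
    a2 <- f[seq(8L, by = 2L, length.out = m)]
    miss <- a1 == "0" | a2 == "0"
    ok1 <- a1 == snps$counted_allele | a1 == snps$other_allele | a1 == "0"
    ok2 <- a2 == snps$counted_allele | a2 == snps$other_allele | a2 == "0"
    if (any(!ok1 | !ok2))
      stop(sprintf("PED line %d: allele not in declared pair for SNP %s",
                   i, snps$snp_id[which(!ok1 | !ok2)[1]]))
    d <- (a1 == snps$counted_allele) + (a2 == snps$counted_allele)
    d[miss] <- NA_integer_
    geno[i, ] <- d
  }
  genotype_dataset(geno, snps, do.call(rbind, ind))
}

read_geno_tsv <- function(prefix) {
  main_path <- paste0(prefix, ".tsv")
  snp_path <- paste0(prefix, ".snps.tsv")
  for (p in c(main_path, snp_path)) if (!file.exists(p)) stop("file not found: ", p)
  snp_tab <- utils::read.delim(snp_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  snps <- snp_info(snp_tab$snp_id, snp_tab$chromosome,
                   as.numeric(snp_tab$position_kb),
                   snp_tab$counted_allele, snp_tab$other_allele)
  tab <- utils::read.delim(main_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta_cols <- c("individual_id", "cohort", "ethnicity", "phenotype")
  if (!all(meta_cols %in% names(tab)))
    stop("TSV must start with columns: ", paste(meta_cols, collapse = ", "))
  if (!all(snps$snp_id %in% names(tab)))
    stop("TSV lacks dosage columns for: ",
         paste(setdiff(snps$snp_id, names(tab)), collapse = ", "))
  geno <- as.matrix(tab[, snps$snp_id, drop = FALSE])
  genotype_dataset(geno, snps, tab[, meta_cols])
}

#' Write genotypes
#'
#' Inverse of [read_genotypes()]; `read(write(x))` reproduces `x` field by
#' field (in the `ped_map` dialect the ethnicity column, which PED cannot
#' carry, is dropped).
#'
#' @param data a [genotype_dataset()].
#' @param prefix output path without extension.
#' @param dialect `"ped_map"` or `"tsv"`.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(data, prefix, dialect = c("ped_map", "tsv")) {
  stopifnot(inherits(data, "genotype_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") {
    map <- data.frame(
      chr = data$snps$chromosome, snp = data$snps$snp_id, cm = 0,
      bp = round(data$snps$position_kb * 1000),
      a1 = data$snps$counted_allele, a2 = data$snps$other_allele
    )
    utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    m <- nrow(data$snps)
    alle <- matrix("0", nrow(data$genotypes), 2L * m)
    for (j in seq_len(m)) {
      d <- data$genotypes[, j]
      a <- ifelse(is.na(d), "0", ifelse(d >= 1, data$snps$counted_allele[j],
                                        data$snps$other_allele[j]))
      b <- ifelse(is.na(d), "0", ifelse(d == 2, data$snps$counted_allele[j],
                                        data$snps$other_allele[j]))
      alle[, 2L * j - 1L] <- a
      alle[, 2L * j] <- b
    }
    ped <- cbind(
      data$individuals$cohort, data$individuals$individual_id, "0", "0", "0",
      ifelse(data$individuals$phenotype == "case", "2", "1"), alle
    )
    utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    snp_tab <- data$snps
    utils::write.table(snp_tab, paste0(prefix, ".snps.tsv"), quote = FALSE,
                       sep = "\t", row.names = FALSE)
    tab <- cbind(data$individuals, as.data.frame(data$genotypes))
    utils::write.table(tab, paste0(prefix, ".tsv"), quote = FALSE,
                       sep = "\t", row.names = FALSE)
  }
  invisible(prefix)
}

#' Read population sampling coordinates
#'
#' @param path CSV with header `population,latitude,longitude`.
#' @param members_path optional CSV with header `individual_id,population`
#'   mapping individuals to populations; stored as a `member_ids`
#'   list-column.
#' @return `data.frame` with columns `population`, `latitude`, `longitude`
#'   and (if supplied) `member_ids`.
#' @export
read_population_table <- function(path, members_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty population table")
    return(data.frame(population = character(), latitude = numeric(),
                      longitude = numeric()))
  }
  need <- c("population", "latitude", "longitude")
  if (!all(need %in% names(tab)))
    stop("population table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$population))
    stop("duplicate population name: ",
         tab$population[duplicated(tab$population)][1])
  if (any(tab$latitude < -90 | tab$latitude > 90))
    stop("latitude out of [-90, 90]")
  if (any(tab$longitude < -180 | tab$longitude > 180))
    stop("longitude out of [-180, 180]")
  tab <- tab[, need]
  if (!is.null(members_path)) {
    mem <- utils::read.csv(members_path, stringsAsFactors = FALSE)
    if (!all(c("individual_id", "population") %in% names(mem)))
      stop("membership table needs columns individual_id, population")
    tab$member_ids <- lapply(tab$population, function(p)
      as.character(mem$individual_id[mem$population == p]))
    if (any(lengths(tab$member_ids) == 0L))
      stop("population with no members: ",
           tab$population[lengths(tab$member_ids) == 0L][1])
  }
  tab
}

#' Write population sampling coordinates
#' @param populations table as from [read_population_table()].
#' @param path output CSV; a `<path>.members.csv` companion is written when a
#'   `member_ids` column is present.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(populations, path) {
  utils::write.csv(populations[, c("population", "latitude", "longitude")],
                   path, row.names = FALSE, quote = TRUE)
  if (!is.null(populations$member_ids)) {
    mem <- data.frame(
      individual_id = unlist(populations$member_ids),
      population = rep(populations$population, lengths(populations$member_ids))
    )
    utils::write.csv(mem, paste0(path, ".members.csv"), row.names = FALSE,
                     quote = TRUE)
  }
  invisible(path)
}

#' Read an ESRD registry prevalence table
#'
#' One row per region with counts of end-stage renal disease (ESRD)
#' attributable to IgA nephropathy: incident cases over the reporting
#' period, point-prevalent cases, total ESRD cases, ESRD cases due to
#' primary glomerulonephritis (GN), and population in millions.
#'
#' @param path CSV with columns `region_name, average_latitude,
#'   incident_count, prevalent_count, total_esrd_count, gn_esrd_count,
#'   population_millions`.
#' @return Validated `data.frame`.
#' @export
read_prevalence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_name", "average_latitude", "incident_count",
            "prevalent_count", "total_esrd_count", "gn_esrd_count",
            "population_millions")
  if (!all(need %in% names(tab)))
    stop("prevalence table needs columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (any(tab$population_millions <= 0))
    stop("population_millions must be > 0")
  cnt <- c("incident_count", "prevalent_count", "total_esrd_count", "gn_esrd_count")
  if (any(tab[cnt] < 0)) stop("counts must be non-negative")
  if (any(tab$prevalent_count > tab$total_esrd_count))
    stop("prevalent_count exceeds total_esrd_count for region: ",
         tab$region_name[tab$prevalent_count > tab$total_esrd_count][1])
  if (any(tab$gn_esrd_count > tab$total_esrd_count))
    stop("gn_esrd_count exceeds total_esrd_count")
  tab
}

#' Write an ESRD registry prevalence table
#' @param records table as from [read_prevalence_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_prevalence_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
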