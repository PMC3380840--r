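test_that("PED/MAP parsing counts the declared allele and maps missing codes", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnp01\t0\t10000\tA\tG",
               "1\tsnp02\t0\t20000\tC\tT"),
             file.path(dir, "toy.map"))
  writeLines(c("f1\tind1\t0\t0\t0\t2\tA A\tC C",
               "f1\tind2\t0\t0\t0\t1\tA G\tC T",
               "f1\tind3\t0\t0\t0\t1\t0 0\tT T"),
             file.path(dir, "toy.ped"))
  d <- read_genotypes(file.path(dir, "toy"), "ped_map")
  expect_equal(unname(d$genotypes[, "snp01"]), c(2L, 1L, NA))
  expect_equal(unname(d$genotypes[, "snp02"]), c(2L, 1L, 0L))
  expect_equal(d$individuals$phenotype, c("case", "control", "control"))
  expect_equal(d$snps$position_kb, c(10, 20))

  # malformed line is reported with its number; foreign allele is a data error
  writeLines(c("f1\tind1\t0\t0\t0\t2\tA A"), file.path(dir, "bad.ped"))
  file.copy(file.path(dir, "toy.map"), file.path(dir, "bad.map"))
  expect_error(read_genotypes(file.path(dir, "bad"), "ped_map"), "line 1")
  writeLines(c("f1\tind1\t0\t0\t0\t2\tA A\tC G"), file.path(dir, "bad.ped"))
  expect_error(read_genotypes(file.path(dir, "bad"), "ped_map"),
               "not in declared pair")
})

test_that("write/read round-trips are the identity in both dialects", {
  d <- random_dataset()
  dir <- withr::local_tempdir()
  for (dialect in c("ped_map", "tsv")) {
    prefix <- file.path(dir, dialect)
    write_genotypes(d, prefix, dialect)
    back <- read_genotypes(prefix, dialect)
    expect_equal(back$genotypes, d$genotypes)
    expect_equal(back$snps, d$snps)
    cols <- c("individual_id", "cohort", "phenotype")
    expect_equal(back$individuals[cols], d$individuals[cols])
    if (dialect == "tsv")
      expect_equal(back$individuals$ethnicity, d$individuals$ethnicity)
  }
})

test_that("flipping the counted allele is involutive and maps d to 2-d", {
  d <- random_dataset(seed = 7)
  f <- flip_counted_allele(d, "rs101")
  expect_equal(f$genotypes[, "rs101"], 2L - d$genotypes[, "rs101"])
  expect_equal(f$snps$counted_allele[1], d$snps$other_allele[1])
  expect_equal(flip_counted_allele(f, "rs101"), d)
})

test_that("population table reader validates coordinates and uniqueness", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "pops.csv")
  writeLines(c("population,latitude,longitude", "Valtrompia,45.7,10.2",
               "Brescia,45.5,10.2"), p)
  tab <- read_population_table(p)
  expect_equal(tab$latitude[tab$population == "Valtrompia"], 45.7)
  expect_equal(nrow(tab), 2)

  writeLines(c("population,latitude,longitude", "A,95,0"), p)
  expect_error(read_population_table(p), "latitude")
  writeLines(c("population,latitude,longitude", "A,10,0", "A,11,0"), p)
  expect_error(read_population_table(p), "duplicate")
  writeLines("population,latitude,longitude", p)
  expect_warning(out <- read_population_table(p), "empty")
  expect_equal(nrow(out), 0)

  # membership mapping round-trip
  writeLines(c("population,latitude,longitude", "A,10,0", "B,20,5"), p)
  m <- file.path(dir, "members.csv")
  writeLines(c("individual_id,population", "i1,A", "i2,A", "i3,B"), m)
  tab <- read_population_table(p, m)
  expect_equal(tab$member_ids[[1]], c("i1", "i2"))
  write_population_table(tab, file.path(dir, "out.csv"))
  back <- read_population_table(file.path(dir, "out.csv"),
                                file.path(dir, "out.csv.members.csv"))
  expect_equal(back, tab)
})

test_that("prevalence table reader validates counts and round-trips", {
  path <- system.file("extdata", "era_edta_igan_esrd_synthetic.csv",
                      package = "igarisk")
  tab <- read_prevalence_table(path)
  expect_equal(nrow(tab), 13)

  dir <- withr::local_tempdir()
  p <- file.path(dir, "prev.csv")
  write_prevalence_table(tab, p)
  expect_equal(read_prevalence_table(p), tab)

  bad <- tab; bad$population_millions[1] <- -1
  write_prevalence_table(bad, p)
  expect_error(read_prevalence_table(p), "population_millions")
  bad <- tab; bad$prevalent_count[2] <- bad$total_esrd_count[2] + 1
  write_prevalence_table(bad, p)
  expect_error(read_prevalence_table(p), "prevalent_count")
})
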