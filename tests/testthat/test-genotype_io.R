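test_that("the packaged family fixture loads with the published structure", {
  fam <- robin_families()
  expect_s3_class(fam, "msat_data")
  expect_equal(nrow(fam$loci), 14)
  expect_equal(sort(unique(fam$families$family)), c("MO6", "WA6", "WE8"))
  broods <- table(fam$families$family)
  expect_equal(as.vector(broods[c("MO6", "WA6", "WE8")]), c(8, 5, 7))
  # one female + one male per family, all resolving in the dataset
  expect_true(all(c(fam$families$mother, fam$families$father) %in% fam$individuals$id))
  expect_equal(sum(fam$individuals$role == "adult"), 6)
  # the only missing genotype is the WE8 male's failed ER25
  miss <- dplyr::filter(fam$genotypes, is.na(allele_1))
  expect_equal(nrow(miss), 1)
  expect_equal(miss$id, "WE8-M")
  expect_equal(miss$locus, "ER25")
})

test_that("degenerate and malformed genotype tables are rejected informatively", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,population,role,L1_1,L1_2", empty)
  expect_error(read_genotype_table(empty), "no individuals")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2", "a,100,100", "a,103,103"), dup)
  expect_error(read_genotype_table(dup), "duplicate.*a")

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2", "a,100,100", "b,103"), ragged)
  expect_error(suppressWarnings(read_genotype_table(ragged)), "row")

  half <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2,L2_1,L2_2", "a,100,xx,90,93"), half)
  # the unparseable field warns, and the now half-scored genotype is
  # demoted to missing with a second warning
  expect_warning(
    expect_warning(x <- read_genotype_table(half), "unparseable"),
    "single scored allele"
  )
  expect_true(all(is.na(dplyr::filter(x$genotypes, locus == "L1")[, c("allele_1", "allele_2")])))
})

test_that("genotype tables and pedigrees round-trip through write/read", {
  sim <- simulate_dataset(sim_config(seed = 11, n_loci = 5, n_families = 3,
    pop_sizes = c(8, 6), epp_rate = 0.5, null_allele_freq = 0.05))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(sim$data, tf)
  back <- read_genotype_table(tf, loci = sim$data$loci)
  expect_equal(
    dplyr::arrange(sim$data$genotypes, id, locus),
    dplyr::arrange(back$genotypes, id, locus)
  )
  expect_equal(sim$data$individuals, dplyr::arrange(back$individuals,
    match(id, sim$data$individuals$id)))

  pf <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(sim$data$families, pf)
  expect_equal(read_pedigree(pf), sim$data$families)
})

test_that("pedigree validation enforces referential and family integrity", {
  ped <- tibble::tibble(
    family = c("WE8", "WE8", "WE8"), mother = "F1", father = "M1",
    offspring = c("o1", "o2", "o3")
  )
  ok <- validate_pedigree(ped, ids = c("F1", "M1", "o1", "o2", "o3"))
  expect_equal(nrow(ok), 3)
  expect_equal(ok$offspring, c("o1", "o2", "o3")) # row order kept
  expect_error(
    validate_pedigree(ped, ids = c("M1", "o1", "o2", "o3")),
    "not in dataset.*F1"
  )
  expect_error(
    validate_pedigree(dplyr::bind_rows(
      ped,
      tibble::tibble(family = "X", mother = "F2", father = "M2", offspring = "o1")
    )),
    "more than once"
  )
  expect_error(
    validate_pedigree(tibble::tibble(
      family = "A", mother = "F1", father = "F1", offspring = "o1"
    )),
    "must differ"
  )
})

test_that("genepop export follows the dialect", {
  g <- geno_tbl(
    rbind(c("100/103", "428/310"), c("103/103", "0/0")),
    ids = c("a1", "b1")
  )
  g$allele_1[g$allele_1 == 0] <- NA
  g$allele_2[is.na(g$allele_1)] <- NA
  g$population <- rep(c("P1", "P2"), each = 2)
  x <- msat_data(g)
  tf <- withr::local_tempfile(fileext = ".gen")
  write_genepop(x, tf, title = "t")
  lines <- readLines(tf)
  expect_equal(lines[1], "t")
  expect_equal(lines[2:3], c("L1", "L2"))
  expect_equal(sum(lines == "Pop"), 2)
  expect_match(lines[5], "^a1 ,  100103 310428$")
  expect_match(lines[7], "^b1 ,  103103 000000$")

  big <- geno_tbl(rbind(c("1000/1000")))
  expect_error(write_genepop(msat_data(big), tf), "999")
})

test_that("allele order and row order never affect downstream statistics", {
  sim <- simulate_dataset(sim_config(seed = 5, n_loci = 4, n_families = 2,
    pop_sizes = c(10, 10)))
  g <- msat_genotypes(sim$data)
  # swap allele order everywhere and shuffle rows
  swapped <- g %>%
    dplyr::mutate(tmp = allele_1, allele_1 = allele_2, allele_2 = tmp) %>%
    dplyr::select(-tmp)
  shuffled <- swapped[sample.int(nrow(swapped)), ]
  x1 <- sim$data
  x2 <- msat_data(shuffled, loci = sim$data$loci, families = sim$data$families)
  expect_equal(heterozygosity(x1), heterozygosity(x2))
  expect_equal(
    allele_frequencies(x1, by = "population"),
    allele_frequencies(x2, by = "population")
  )
  expect_equal(fst_wc(x1)$theta, fst_wc(x2)$theta)
})
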