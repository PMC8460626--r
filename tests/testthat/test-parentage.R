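test_that("trio verdicts match the exhaustive-partition oracle", {
  # every combination of genotypes over a 2-allele locus, plus spot checks
  # with a third allele
  genos <- list(c(1, 1), c(1, 2), c(2, 2))
  for (off in genos) {
    for (mom in genos) {
      for (dad in genos) {
        expect_equal(
          check_trio(off, mom, dad), oracle_trio(off, mom, dad),
          info = paste(off[1], off[2], "|", mom[1], mom[2], "|", dad[1], dad[2])
        )
      }
    }
  }
  set.seed(23)
  for (rep in 1:200) {
    off <- sort(sample(1:3, 2, TRUE))
    mom <- sort(sample(1:3, 2, TRUE))
    dad <- sort(sample(1:3, 2, TRUE))
    expect_equal(check_trio(off, mom, dad), oracle_trio(off, mom, dad))
  }
})

test_that("the homozygous-mother-cover case excludes the father", {
  # both offspring alleles occur in the mother, father carries neither:
  # every maternal partition leaves a paternal allele the father lacks
  expect_equal(check_trio(c(140, 155), c(140, 155), c(137, 137)), "father_mismatch")
  # a Mendelian cross is compatible
  expect_equal(check_trio(c(140, 137), c(140, 155), c(137, 137)), "compatible")
  # missing data is untestable
  expect_equal(check_trio(c(NA, NA), c(140, 155), c(137, 137)), "untestable")
})

test_that("verdicts are invariant to allele order within genotypes", {
  set.seed(24)
  for (rep in 1:100) {
    off <- sample(1:4, 2, TRUE)
    mom <- sample(1:4, 2, TRUE)
    dad <- sample(1:4, 2, TRUE)
    v <- check_trio(off, mom, dad)
    expect_equal(check_trio(rev(off), mom, dad), v)
    expect_equal(check_trio(off, rev(mom), dad), v)
    expect_equal(check_trio(off, mom, rev(dad)), v)
  }
})

test_that("families simulated without EPP, nulls or errors are fully compatible", {
  cfg <- sim_config(seed = 25, n_loci = 14, n_families = 30,
    offspring_range = c(5, 8), epp_rate = 0)
  sim <- simulate_families(draw_allele_frequencies(cfg), cfg)
  fit <- parentage(sim$data)
  expect_true(all(fit$offspring$classification == "within_pair"))
  expect_equal(sum(fit$offspring$n_father_mismatch), 0)
  expect_equal(sum(fit$offspring$n_mother_mismatch), 0)
  expect_equal(epp_summary(fit)$family_rate, 0)
})

test_that("simulated extra-pair offspring are recovered from the truth record", {
  cfg <- sim_config(seed = 26, n_loci = 14, n_families = 15,
    epp_rate = 0.5, epp_nestling_fraction = 0.4, allele_range = c(9, 26))
  sim <- simulate_families(draw_allele_frequencies(cfg), cfg)
  fit <- parentage(sim$data)
  truth <- sim$truth$offspring
  got <- fit$offspring$classification[match(truth$offspring, fit$offspring$offspring)]
  # with 14 highly polymorphic loci, exclusion recovers the truth
  expect_equal(got == "extra_pair", truth$sire == "extra_pair")
})

test_that("exclusion is monotone in the locus panel", {
  cfg <- sim_config(seed = 27, n_loci = 14, n_families = 10, epp_rate = 0.7)
  sim <- simulate_families(draw_allele_frequencies(cfg), cfg)
  full <- parentage(sim$data)
  # drop half the panel
  keep <- sim$data$loci$locus[1:7]
  sub <- msat_data(
    dplyr::filter(msat_genotypes(sim$data), locus %in% keep),
    loci = dplyr::filter(sim$data$loci, locus %in% keep),
    families = sim$data$families
  )
  part <- parentage(sub)
  ep_small <- part$offspring$offspring[part$offspring$classification == "extra_pair"]
  ep_full <- full$offspring$offspring[full$offspring$classification == "extra_pair"]
  expect_true(all(ep_small %in% ep_full))
})

test_that("family-level errors and summaries behave", {
  fam <- robin_families()
  expect_error(analyze_family(fam, "ZZ9"), "unknown family")
  bad_ped <- tibble::tibble(
    family = "MO6", mother = "MO6-F", father = "MO6-M", offspring = "ghost"
  )
  expect_error(parentage(fam, families = bad_ped), "ghost")

  # hand-constructed summaries: 1 EPP family of 7 and 2 EP nestlings of 48
  off <- tibble::tibble(
    family = rep(sprintf("f%d", 1:7), each = 7)[1:48],
    offspring = sprintf("o%d", 1:48),
    classification = c(rep("extra_pair", 2), rep("within_pair", 46))
  )
  s <- epp_summary(off)
  expect_equal(s$n_epp_families, 1)
  expect_equal(round(100 * s$family_rate, 1), 14.3)
  expect_equal(round(100 * s$offspring_rate, 1), 4.2)

  zero <- epp_summary(dplyr::mutate(off, classification = "within_pair"))
  expect_equal(zero$family_rate, 0)
  expect_equal(zero$offspring_rate, 0)
})

test_that("the maternal audit agrees with trio verdicts", {
  fam <- robin_families()
  audit <- maternal_audit(fam)
  fit <- parentage(fam)
  joined <- dplyr::left_join(
    audit, fit$verdicts,
    by = c("family", "offspring", "locus")
  )
  testable <- dplyr::filter(joined, !is.na(non_paternal))
  expect_equal(
    testable$non_paternal,
    testable$verdict == "father_mismatch"
  )
  # hand cases
  x <- msat_data(
    geno_tbl(rbind("1/2", "1/1", "2/3", "1/2"), ids = c("off", "mom", "dad", "off2")),
    families = tibble::tibble(
      family = "f", mother = "mom", father = "dad", offspring = "off"
    )
  )
  a <- maternal_audit(x)
  expect_equal(a$maternal_options, "1")
  expect_false(a$ambiguous)
  x2 <- msat_data(
    geno_tbl(rbind("1/2", "1/2", "2/3"), ids = c("off", "mom", "dad")),
    families = tibble::tibble(
      family = "f", mother = "mom", father = "dad", offspring = "off"
    )
  )
  expect_true(maternal_audit(x2)$ambiguous)
})

test_that("tidy, glance and autoplot methods work on parentage fits", {
  fit <- parentage(robin_families())
  expect_equal(tidy(fit), fit$offspring)
  expect_equal(glance(fit), epp_summary(fit))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
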