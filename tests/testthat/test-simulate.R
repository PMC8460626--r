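test_that("frequency draws are valid, ladder-bound and deterministic under seed", {
  cfg <- sim_config(seed = 31, n_loci = 8)
  f1 <- draw_allele_frequencies(cfg)
  f2 <- draw_allele_frequencies(cfg)
  expect_equal(f1, f2)
  sums <- tapply(f1$freq, f1$locus, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # alleles per locus within the configured range, sizes on the motif ladder
  per <- f1 %>% dplyr::count(locus, motif_length)
  expect_true(all(per$n >= 9 & per$n <= 26))
  steps <- f1 %>%
    dplyr::group_by(locus) %>%
    dplyr::summarise(ok = all(diff(allele) %% motif_length[1] == 0))
  expect_true(all(steps$ok))
})

test_that("a fixed panel that cannot hold the drawn alleles is an error", {
  tight <- tibble::tibble(
    locus = "L1", motif_length = 3, size_min = 100, size_max = 112
  )
  cfg <- sim_config(seed = 1, n_loci = 1, allele_range = c(10, 10), size_ranges = tight)
  expect_error(draw_allele_frequencies(cfg), "cannot hold")
})

test_that("large Dirichlet concentration approaches equifrequency", {
  cfg <- sim_config(seed = 32, n_loci = 4, allele_range = c(10, 10),
    concentration = 1e5)
  f <- draw_allele_frequencies(cfg)
  expect_true(all(abs(f$freq - 0.1) < 0.01))
})

test_that("inbreeding limits of the population sampler", {
  cfg <- sim_config(seed = 33, n_loci = 6, allele_range = c(5, 10))
  freqs <- draw_allele_frequencies(cfg)
  hwe <- sample_population(freqs, 400, f = 0, seed = 34)
  h <- heterozygosity(hwe)
  exp_het <- allele_frequencies(hwe) %>%
    dplyr::group_by(locus) %>%
    dplyr::summarise(he = 1 - sum(freq^2))
  expect_lt(max(abs(h$H_O - exp_het$he[match(h$locus, exp_het$locus)])), 0.08)
  all_hom <- sample_population(freqs, 50, f = 1, seed = 35)
  g <- msat_genotypes(all_hom)
  expect_true(all(g$allele_1 == g$allele_2))
})

test_that("the population pair sampler hits its differentiation targets", {
  cfg <- sim_config(seed = 36, n_loci = 14)
  freqs <- draw_allele_frequencies(cfg)
  null_pair <- sample_population_pair(freqs, 60, 60, fst = 0, seed = 37)
  expect_lt(abs(fst_wc(null_pair)$theta), 0.02)
  strong <- sample_population_pair(freqs, 100, 100, fst = 0.5, seed = 38)
  th <- fst_wc(strong)$theta
  expect_gt(th, 0.35)
  expect_lt(th, 0.65)
})

test_that("family simulation truth is consistent with the emitted genotypes", {
  cfg <- sim_config(seed = 39, n_loci = 10, n_families = 12, epp_rate = 0.3)
  sim <- simulate_families(draw_allele_frequencies(cfg), cfg)
  expect_equal(nrow(sim$truth$offspring), nrow(sim$data$families))
  expect_equal(nrow(sim$truth$events), 0) # no nulls or errors configured
  # with clean data, every within-pair offspring is trio-compatible at all loci
  fit <- parentage(sim$data)
  wp <- sim$truth$offspring$offspring[sim$truth$offspring$sire == "social"]
  counts <- fit$offspring[match(wp, fit$offspring$offspring), ]
  expect_true(all(counts$n_father_mismatch == 0))
  expect_true(all(counts$n_mother_mismatch == 0))
})

test_that("null alleles and scoring errors are logged and visible", {
  cfg <- sim_config(seed = 40, n_loci = 8, n_families = 10,
    null_allele_freq = 0.15, genotyping_error = 0.02)
  sim <- simulate_families(draw_allele_frequencies(cfg), cfg)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$event %in% c("null_masked", "null_dropout", "scoring_error")))
  # homozygous null carriers appear as missing genotypes
  drop <- dplyr::filter(ev, event == "null_dropout")
  if (nrow(drop) > 0) {
    g <- sim$data$genotypes
    miss <- g[paste(g$id, g$locus) %in% paste(drop$id, drop$locus), ]
    expect_true(all(is.na(miss$allele_1)))
  }
})

test_that("simulated datasets are internally valid and reproducible", {
  cfg <- sim_config(seed = 41, n_loci = 5, n_families = 3, pop_sizes = c(10, 8))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(s1$data$genotypes, s2$data$genotypes)
  expect_equal(s1$truth$offspring, s2$truth$offspring)
  # populations partition individuals; families resolve
  expect_equal(
    sort(unique(s1$data$individuals$population)),
    c("families", "pop1", "pop2")
  )
  expect_true(all(s1$data$families$offspring %in% s1$data$individuals$id))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(epp_rate = 1.2), "rates")
  expect_error(sim_config(fst = 1), "below 1")
  expect_error(sim_config(motif_lengths = 2))
})
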