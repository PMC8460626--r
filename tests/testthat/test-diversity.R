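test_that("allele frequencies count gene copies and conserve mass", {
  x <- geno_tbl(rbind("100/103", "100/100"))
  f <- allele_frequencies(x)
  expect_equal(f$freq[f$allele == 100], 0.75)
  expect_equal(f$freq[f$allele == 103], 0.25)
  expect_equal(unique(f$n_typed), 2L)

  mono <- allele_frequencies(geno_tbl(rbind("100/100", "100/100")))
  expect_equal(mono$freq, 1)

  sim <- simulate_dataset(sim_config(seed = 2, n_loci = 6, n_families = 2,
    pop_sizes = c(12, 9), null_allele_freq = 0.1))
  sums <- allele_frequencies(sim$data, by = "population") %>%
    dplyr::group_by(locus, population) %>%
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("heterozygosity matches the unbiased small-sample form", {
  # two individuals, both heterozygous A/B: H_O = 1, H_E = (4/3) * 0.5
  x <- geno_tbl(rbind("100/103", "100/103"))
  h <- heterozygosity(x)
  expect_equal(h$H_O, 1)
  expect_equal(h$H_E, 4 / 3 * 0.5, tolerance = 1e-12)

  mono <- heterozygosity(geno_tbl(rbind("100/100", "100/100")))
  expect_equal(mono$H_O, 0)
  expect_equal(mono$H_E, 0)

  # single individual: unbiased H_E undefined
  one <- heterozygosity(geno_tbl(rbind("100/103")))
  expect_true(is.na(one$H_E))

  # properties over random datasets: bounds and the unbiased >= biased relation
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    p <- rand_freqs(k)
    n <- sample(5:40, 1)
    a1 <- sample(seq_len(k), n, TRUE, prob = p)
    a2 <- sample(seq_len(k), n, TRUE, prob = p)
    g <- tibble::tibble(
      id = sprintf("i%d", 1:n), locus = "L1",
      allele_1 = pmin(a1, a2) + 99L, allele_2 = pmax(a1, a2) + 99L
    )
    h <- heterozygosity(g)
    f <- allele_frequencies(g)
    expect_gte(h$H_O, 0)
    expect_lte(h$H_O, 1)
    expect_gte(h$H_E, 1 - sum(f$freq^2))
    expect_lte(h$H_E, 1)
  }
})

test_that("Bonferroni thresholds reproduce reported precision", {
  expect_equal(bonferroni_threshold(0.05, 14), 0.00357)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 280), 0.000179)
})

test_that("null-allele estimators behave as documented", {
  expect_equal(null_allele_freq(0.8, 0.8), 0)
  expect_equal(null_allele_freq(0.8, 0.6), 0.2 / 1.8)
  expect_equal(null_allele_freq(0.8, 0.6, "chakraborty"), 0.2 / 1.4)
  # heterozygote excess gives a negative estimate (sign only)
  expect_lt(null_allele_freq(0.889, 0.913), 0)
  expect_error(null_allele_freq(0.8, 0.6, "nope"))
})

test_that("rarefied allelic richness equals the exhaustive-subsampling mean", {
  # tiny samples where every subsample can be enumerated
  set.seed(7)
  for (rep in 1:10) {
    n <- 4 # 2N = 8 gene copies
    a1 <- sample(1:4, n, TRUE)
    a2 <- sample(1:4, n, TRUE)
    g <- tibble::tibble(
      id = sprintf("i%d", 1:n), locus = "L1",
      allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2)
    )
    for (gg in c(2, 4, 6)) {
      r <- allelic_richness(g, g = gg, by = NULL)
      expect_equal(r$R, oracle_richness(c(a1, a2), gg), tolerance = 1e-12)
    }
  }
})

test_that("allelic richness limits: full sample and monomorphic locus", {
  x <- geno_tbl(rbind("100/103", "106/109", "100/100"))
  r_full <- allelic_richness(x, g = 6, by = NULL)
  expect_equal(r_full$R, r_full$A) # g = 2N recovers the allele count
  mono <- geno_tbl(rbind("100/100", "100/100", "100/100"))
  expect_equal(allelic_richness(mono, g = 2, by = NULL)$R, 1)
  expect_error(allelic_richness(x, g = 1, by = NULL), "at least 2")
  expect_error(allelic_richness(x, g = 40, by = NULL), "exceeds")
})

test_that("per-locus diversity summary has coherent columns", {
  sim <- simulate_dataset(sim_config(seed = 9, n_loci = 4, n_families = 2,
    pop_sizes = c(15, 10), allele_range = c(3, 5)))
  d <- locus_diversity(sim$data, hwe_args = list(B = 500, seed = 1))
  expect_equal(nrow(d), 4)
  expect_true(all(d$H_O >= 0 & d$H_O <= 1))
  expect_true(all(d$H_E >= 0 & d$H_E <= 1))
  expect_true(all(d$hwe_p >= 0 & d$hwe_p <= 1))
  expect_equal(d$f_null, null_allele_freq(d$H_E, d$H_O))
})

test_that("fully monomorphic panels degrade gracefully", {
  mono <- geno_tbl(rbind(
    c("100/100", "200/200"),
    c("100/100", "200/200"),
    c("100/100", "200/200")
  ))
  h <- heterozygosity(mono)
  expect_equal(h$H_E, c(0, 0))
  hw <- hwe_test(mono)
  expect_equal(hw$p_value, c(1, 1))
  expect_false(any(hw$testable))
  f <- fis_wc(mono)
  expect_true(all(is.na(f$F_IS)))
})
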