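test_that("planted repeats are reported with exact coordinates", {
  s <- c(x = paste0(strrep("C", 30), strrep("ACG", 5), strrep("T", 30)))
  hits <- find_ssrs(s)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif_found, "ACG")
  expect_equal(hits$n_repeats, 5L)
  expect_equal(hits$start, 31L)
  expect_equal(hits$end, 45L)
  expect_equal(hits$end - hits$start + 1L, hits$motif_length * hits$n_repeats)
  expect_equal(hits$flank_left, 30L)
  expect_equal(hits$flank_right, 30L)
})

test_that("the five-repeat threshold is a hard boundary", {
  four <- c(x = paste0(strrep("C", 30), strrep("AGAT", 4), strrep("T", 30)))
  five <- c(x = paste0(strrep("C", 30), strrep("AGAT", 5), strrep("T", 30)))
  expect_equal(nrow(find_ssrs(four)), 0)
  expect_equal(nrow(find_ssrs(five)), 1)
})

test_that("homopolymers and periodic pseudo-motifs are suppressed", {
  s <- c(
    a = paste0(strrep("G", 10), strrep("A", 40), strrep("G", 10)),
    b = paste0(strrep("G", 10), strrep("AC", 12), strrep("G", 10))
  )
  expect_equal(nrow(find_ssrs(s)), 0) # period-1 and period-2 runs only
})

test_that("invalid characters are rejected by position; N breaks runs", {
  expect_error(find_ssrs(c(x = "ACGTXACGT")), "position 5")
  s <- c(x = paste0(strrep("C", 20), strrep("AGT", 3), "N", strrep("AGT", 3), strrep("C", 20)))
  expect_equal(nrow(find_ssrs(s)), 0) # neither side reaches 5 repeats
})

test_that("the scanner equals the brute-force oracle on random sequences", {
  set.seed(41)
  for (rep in 1:8) {
    s <- random_dna(2000, gc = runif(1, 0.3, 0.7))
    hits <- find_ssrs(c(x = s), min_repeats = 3)
    oracle <- brute_ssr(s, min_repeats = 3)
    hits <- dplyr::arrange(hits, motif_length, start)
    cols <- c("motif", "n_repeats", "start", "end")
    expect_equal(
      as.data.frame(hits[, cols]), as.data.frame(oracle[, cols]),
      ignore_attr = TRUE
    )
  }
})

test_that("canonical motifs make scanning strand-consistent", {
  gen <- generate_ssr_sequences(n_seqs = 3, length = 600, plants_per_seq = 2, seed = 43)
  fwd <- find_ssrs(gen$sequences)
  rc <- find_ssrs(vapply(gen$sequences, revcomp, ""))
  expect_equal(
    sort(paste(fwd$seq_id, fwd$motif, fwd$n_repeats)),
    sort(paste(rc$seq_id, rc$motif, rc$n_repeats))
  )
  expect_equal(canonical_motif("TCT"), canonical_motif("AGA"))
  expect_equal(canonical_motif("GATA"), "AGAT")
})

test_that("the filter cascade screens on flanks, Tm difference and windows", {
  # too little flanking sequence
  tight <- c(x = paste0(strrep("C", 10), strrep("AGAT", 8), strrep("T", 10)))
  sc <- screen_candidates(find_ssrs(tight), tight)
  expect_false(sc$pass)
  expect_equal(sc$first_failed, "insufficient_flank")

  # generous flanks: a pair passes, with both primers inside all windows
  gen <- generate_ssr_sequences(n_seqs = 2, length = 700, plants_per_seq = 1,
    min_flank = 150, seed = 44)
  hits <- find_ssrs(gen$sequences)
  sc2 <- screen_candidates(hits, gen$sequences)
  passed <- dplyr::filter(sc2, pass)
  expect_gt(nrow(passed), 0)
  expect_true(all(passed$tm_diff <= 2))
  expect_true(all(passed$tm_fwd >= 58 & passed$tm_fwd <= 62))
  expect_true(all(passed$gc_fwd >= 0.3 & passed$gc_fwd <= 0.7))
  expect_true(all(passed$product_size >= 100 & passed$product_size <= 350))
  expect_true(all(nchar(passed$fwd_primer) %in% 18:22))

  # an impossible Tm-difference criterion rejects every pair
  sc3 <- screen_candidates(hits, gen$sequences,
    criteria = list(max_tm_diff = -1))
  expect_false(any(sc3$pass))
  # screening is idempotent: rescreening the survivors changes nothing
  sc4 <- screen_candidates(passed[, names(hits)], gen$sequences)
  expect_equal(sc4$pass, rep(TRUE, nrow(passed)))
  expect_equal(sc4$penalty, passed$penalty)
})

test_that("melting temperatures are physically plausible and length-monotone", {
  expect_gt(primer_tm("ACGTACGTACGTACGTACGT"), 40)
  expect_lt(primer_tm("ACGTACGTACGTACGTACGT"), 75)
  # GC-rich melts higher than AT-rich at the same length
  expect_gt(primer_tm(strrep("GC", 10)), primer_tm(strrep("AT", 10)))
  expect_equal(gc_content("GGCCAATT"), 0.5)
})

test_that("multiplex grouping partitions totally with closed medium bounds", {
  x <- tibble::tibble(product_size = c(150, 200, 250, 300, 350))
  g <- group_for_multiplex(x)
  expect_equal(as.character(g$size_group), c("short", "medium", "medium", "medium", "long"))
  set.seed(45)
  y <- tibble::tibble(product_size = sample(80:450, 100, TRUE))
  gy <- group_for_multiplex(y)
  expect_false(any(is.na(gy$size_group)))
  expect_equal(
    sum(gy$size_group == "short") + sum(gy$size_group == "medium") +
      sum(gy$size_group == "long"),
    100
  )
})
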