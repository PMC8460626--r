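# Independent oracles and small builders used across the test files.
# Each oracle re-derives the quantity from first principles by brute force,
# on a code path disjoint from the package implementation.

# random frequency vector of k alleles (flat Dirichlet)
rand_freqs <- function(k) {
  w <- rgamma(k, 1)
  w / sum(w)
}

# quick long-format genotype tibble from a matrix of "a/b" strings
# (rows = individuals, cols = loci)
geno_tbl <- function(mat, population = "pop1", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(mat)))
  loci <- colnames(mat)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(mat)))
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    parts <- strsplit(mat[i, ], "/")
    tibble::tibble(
      id = ids[i], population = population, role = "adult", unrelated = TRUE,
      locus = loci,
      allele_1 = as.integer(vapply(parts, `[`, "", 1)),
      allele_2 = as.integer(vapply(parts, `[`, "", 2))
    )
  })
}

# ---- Hardy-Weinberg oracle -------------------------------------------------
# Exact conditional distribution of genotype arrays given allele counts,
# derived by enumerating every perfect matching of the 2n labelled gene
# copies (no Levene formula involved).
pairings_distribution <- function(copies) {
  counts <- new.env(parent = emptyenv())
  recurse <- function(idx, key_parts) {
    if (length(idx) == 0) {
      key <- paste(sort(key_parts), collapse = ";")
      prev <- counts[[key]]
      counts[[key]] <- if (is.null(prev)) 1 else prev + 1
      return(invisible())
    }
    first <- idx[1]
    rest <- idx[-1]
    for (m in seq_along(rest)) {
      pair <- sort(c(copies[first], copies[rest[m]]))
      recurse(rest[-m], c(key_parts, paste(pair, collapse = "-")))
    }
  }
  recurse(seq_along(copies), character(0))
  keys <- ls(counts)
  n <- vapply(keys, function(k) counts[[k]], numeric(1))
  tibble::tibble(array = keys, prob = n / sum(n))
}

# oracle p-value of the probability test for an observed genotype set
oracle_hwe_p <- function(a1, a2) {
  copies <- c(a1, a2)
  dist <- pairings_distribution(copies)
  obs_key <- paste(
    sort(vapply(
      seq_along(a1),
      function(i) paste(sort(c(a1[i], a2[i])), collapse = "-"), ""
    )),
    collapse = ";"
  )
  p_obs <- dist$prob[dist$array == obs_key]
  sum(dist$prob[dist$prob <= p_obs + 1e-12])
}

# all allele-count configurations (compositions of 2n over k alleles)
allele_count_configs <- function(n, k) {
  total <- 2 * n
  if (k == 2) {
    lapply(seq_len(total - 1), function(m1) c(m1, total - m1))
  } else {
    out <- list()
    for (m1 in seq_len(total - 2)) {
      for (m2 in seq_len(total - m1 - 1)) {
        out[[length(out) + 1]] <- c(m1, m2, total - m1 - m2)
      }
    }
    out
  }
}

# reconstruct one genotype vector pair from an array key "a-b;c-d;..."
genotypes_from_key <- function(key) {
  pairs <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  list(
    a1 = as.integer(vapply(pairs, `[`, "", 1)),
    a2 = as.integer(vapply(pairs, `[`, "", 2))
  )
}

# ---- non-exclusion Monte-Carlo oracle --------------------------------------
# straight simulation of the three scenarios; its trio logic is written out
# directly rather than calling check_trio()/non_exclusion()
mc_non_exclusion <- function(p, scenario, B = 1e5) {
  k <- length(p)
  draw <- function(n) sample.int(k, n, replace = TRUE, prob = p)
  if (scenario == "first_parent") {
    o1 <- draw(B)
    o2 <- draw(B)
    c1 <- draw(B)
    c2 <- draw(B)
    ok <- c1 == o1 | c1 == o2 | c2 == o1 | c2 == o2
    return(mean(ok))
  }
  if (scenario == "second_parent") {
    m1 <- draw(B)
    m2 <- draw(B)
    mat <- ifelse(stats::runif(B) < 0.5, m1, m2) # transmitted maternal allele
    pat <- draw(B)
    c1 <- draw(B)
    c2 <- draw(B)
    ok <- logical(B)
    for (i in seq_len(B)) {
      off <- c(mat[i], pat[i])
      mom <- c(m1[i], m2[i])
      cand <- c(c1[i], c2[i])
      # any split: one offspring allele via mother, the other via candidate
      ok[i] <- (off[1] %in% mom && off[2] %in% cand) ||
        (off[2] %in% mom && off[1] %in% cand)
    }
    return(mean(ok))
  }
  if (scenario == "parent_pair") {
    # one allele per true parent: marginally two independent HWE draws
    o1 <- draw(B)
    o2 <- draw(B)
    M1 <- draw(B)
    M2 <- draw(B)
    F1 <- draw(B)
    F2 <- draw(B)
    in_M <- function(x) x == M1 | x == M2
    in_F <- function(x) x == F1 | x == F2
    ok <- (in_M(o1) & in_F(o2)) | (in_M(o2) & in_F(o1))
    return(mean(ok))
  }
  stop("unknown scenario")
}

# ---- trio verdict oracle ---------------------------------------------------
# exhaustive-partition definition of the trio verdict
oracle_trio <- function(off, mom, dad) {
  if (anyNA(c(off, mom, dad))) {
    return("untestable")
  }
  perms <- list(c(1, 2), c(2, 1))
  compatible <- any(vapply(perms, function(pr) {
    off[pr[1]] %in% mom && off[pr[2]] %in% dad
  }, logical(1)))
  if (compatible) {
    return("compatible")
  }
  if (!any(off %in% mom)) {
    return("mother_mismatch")
  }
  "father_mismatch"
}

# ---- brute-force SSR scanner oracle ----------------------------------------
# per-position substring comparisons: for every candidate start and motif
# length, verify left-maximality and count complete copies of the motif
brute_ssr <- function(s, min_repeats = 5, motif_lengths = c(3, 4)) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  out <- list()
  for (k in motif_lengths) {
    for (a in seq_len(max(0, L - k * min_repeats + 1))) {
      if (any(!chars[a:(a + k - 1)] %in% c("A", "C", "G", "T"))) next
      # left-maximal periodic region start?
      if (a > 1 && a - 1 + k <= L && chars[a - 1] == chars[a - 1 + k] &&
        chars[a - 1] %in% c("A", "C", "G", "T")) {
        next
      }
      # extent of the periodic region from a
      t <- a
      while (t + k <= L && chars[t] %in% c("A", "C", "G", "T") &&
        chars[t] == chars[t + k]) {
        t <- t + 1
      }
      total <- (t - a) + k
      reps <- total %/% k
      if (reps < min_repeats) next
      motif <- paste(chars[a:(a + k - 1)], collapse = "")
      # not a repetition of a shorter unit
      is_periodic <- FALSE
      for (d in seq_len(k - 1)) {
        if (k %% d == 0 &&
          identical(chars[a:(a + k - d - 1)], chars[(a + d):(a + k - 1)])) {
          is_periodic <- TRUE
          break
        }
      }
      if (is_periodic) next
      out[[length(out) + 1]] <- tibble::tibble(
        motif = canonical_motif(motif), motif_length = k,
        n_repeats = reps, start = a, end = a + k * reps - 1
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      motif = character(), motif_length = integer(),
      n_repeats = integer(), start = integer(), end = integer()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), motif_length, start)
}

# ---- misc ------------------------------------------------------------------
# mean allele count over all gene-copy subsamples of size g (exhaustive)
oracle_richness <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}
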