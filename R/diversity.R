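#' Per-locus allele frequencies
#'
#' Counts each non-missing diploid genotype as two gene copies; missing
#' genotypes are dropped locus-wise, so the number of typed gene copies may
#' differ between loci.
#'
#' @param x An [msat_data] object or long genotype tibble
#'   (see [msat_genotypes()]).
#' @param by Optional grouping column, typically `"population"`; `NULL`
#'   pools the whole sample.
#' @param unrelated_only Restrict to the flagged "unrelated" subset, the
#'   basis the published panel statistics use.
#' @return A tibble with columns `locus` (then the `by` column), `allele`,
#'   `count`, `freq` and `n_typed` (diploid individuals typed at the locus).
#'   Frequencies sum to 1 within each locus (and group). Loci with zero
#'   typed individuals in a group are absent from the result.
#' @export
#' @examples
#' allele_frequencies(robin_families())
allele_frequencies <- function(x, by = NULL, unrelated_only = FALSE) {
  g <- msat_genotypes(x, unrelated_only = unrelated_only) %>%
    dplyr::filter(!is.na(.data$allele_1))
  keys <- c("locus", by)
  long <- g %>%
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") %>%
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$allele, name = "count")
  long %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::mutate(
      freq = .data$count / sum(.data$count),
      n_typed = as.integer(sum(.data$count) / 2)
    ) %>%
    dplyr::ungroup()
}

# named list of frequency vectors, one per locus (optionally per group)
freq_split <- function(freqs, by = NULL) {
  key <- if (is.null(by)) freqs$locus else paste(freqs$locus, freqs[[by]], sep = "\r")
  split(stats::setNames(freqs$freq, freqs$allele), key)
}

#' Observed and unbiased expected heterozygosity
#'
#' H_O is the fraction of typed individuals that are heterozygous; H_E is
#' the unbiased (small-sample corrected) expected heterozygosity
#' `2N/(2N - 1) * (1 - sum(p_i^2))` computed from sample allele frequencies.
#' With fewer than two typed individuals H_E is undefined and reported `NA`.
#'
#' @inheritParams allele_frequencies
#' @return A tibble with `locus` (then `by`), `n` (typed individuals), `A`
#'   (allele count), `H_O`, `H_E`.
#' @export
heterozygosity <- function(x, by = NULL, unrelated_only = FALSE) {
  g <- msat_genotypes(x, unrelated_only = unrelated_only) %>%
    dplyr::filter(!is.na(.data$allele_1))
  keys <- c("locus", by)
  obs <- g %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n = dplyr::n(),
      H_O = mean(.data$allele_1 != .data$allele_2),
      .groups = "drop"
    )
  exp <- allele_frequencies(x, by = by, unrelated_only = unrelated_only) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      A = dplyr::n(),
      H_E = {
        n2 <- sum(.data$count)
        if (n2 >= 4) n2 / (n2 - 1) * (1 - sum(.data$freq^2)) else NA_real_
      },
      .groups = "drop"
    )
  dplyr::left_join(obs, exp, by = keys) %>%
    dplyr::select(dplyr::all_of(keys), "n", "A", "H_O", "H_E")
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies, computed by
#' hypergeometric rarefaction:
#' `R_g = sum_i (1 - choose(2N - N_i, g) / choose(2N, g))`
#' with `N_i` the sample count of allele i. Rarefaction makes allele counts
#' comparable between populations of unequal size.
#'
#' @inheritParams allele_frequencies
#' @param g Rarefaction size in gene copies. Default: the per-locus minimum
#'   number of typed gene copies across the groups, so every group is
#'   rarefied to the smallest sample actually typed at that locus.
#' @return A tibble with `locus` (then `by`), `n_copies`, `g`, `A`, `R`.
#'   `R <= A`, with equality when `g` equals the full sample.
#' @export
allelic_richness <- function(x, g = NULL, by = "population", unrelated_only = FALSE) {
  if (!is.null(g) && g < 2) abort("rarefaction size g must be at least 2")
  freqs <- allele_frequencies(x, by = by, unrelated_only = unrelated_only)
  keys <- c("locus", by)
  sizes <- freqs %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(n_copies = sum(.data$count), .groups = "drop") %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::mutate(g_locus = if (is.null(.env$g)) min(.data$n_copies) else as.integer(.env$g)) %>%
    dplyr::ungroup()
  if (any(sizes$g_locus > sizes$n_copies)) {
    abort("rarefaction size g exceeds the typed gene copies of some group")
  }
  freqs %>%
    dplyr::left_join(sizes, by = keys) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n_copies = .data$n_copies[1],
      g = .data$g_locus[1],
      A = dplyr::n(),
      R = {
        n2 <- .data$n_copies[1]
        gg <- .data$g_locus[1]
        sum(1 - exp(lchoose(n2 - .data$count, gg) - lchoose(n2, gg)))
      },
      .groups = "drop"
    )
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Nominal level, in (0, 1).
#' @param k Number of tests.
#' @param digits Significant digits used in reports (default 3, matching
#'   the precision of the published tables).
#' @return `signif(alpha / k, digits)`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 14) # 0.00357
bonferroni_threshold <- function(alpha = 0.05, k, digits = 3) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  signif(alpha / k, digits)
}

#' Null-allele frequency from the heterozygote deficit
#'
#' Closed-form estimators of the frequency of a non-amplifying allele:
#' Brookfield's first estimator `(H_E - H_O) / (1 + H_E)` (default), or
#' Chakraborty's `(H_E - H_O) / (H_E + H_O)`. Negative estimates (from a
#' heterozygote excess) are allowed and meaningful as "no evidence of a
#' null". Iterative maximum-likelihood estimators (as used by common
#' parentage software) give slightly different values.
#'
#' @param H_E,H_O Expected and observed heterozygosities (vectorised).
#' @param method `"brookfield1"` or `"chakraborty"`.
#' @return Estimated null-allele frequency (same length as input).
#' @export
null_allele_freq <- function(H_E, H_O, method = c("brookfield1", "chakraborty")) {
  method <- match.arg(method)
  switch(method,
    brookfield1 = (H_E - H_O) / (1 + H_E),
    chakraborty = (H_E - H_O) / (H_E + H_O)
  )
}

#' Per-locus diversity summary
#'
#' One row per locus with the statistics of a marker characterisation
#' table: typed sample size, allele count, observed and unbiased expected
#' heterozygosity, Weir-Cockerham fixation index, exact Hardy-Weinberg
#' p-value and the closed-form null-allele frequency estimate.
#'
#' @inheritParams allele_frequencies
#' @param hwe_args List of arguments passed on to [hwe_test()].
#' @return A tibble with columns `locus`, `n`, `A`, `H_O`, `H_E`, `F_IS`,
#'   `hwe_p`, `f_null`.
#' @export
#' @examples
#' locus_diversity(robin_families(), unrelated_only = TRUE)
locus_diversity <- function(x, unrelated_only = FALSE, hwe_args = list()) {
  het <- heterozygosity(x, unrelated_only = unrelated_only)
  fis <- fis_wc(x, unrelated_only = unrelated_only)
  hwe <- do.call(hwe_test, c(list(x, unrelated_only = unrelated_only), hwe_args))
  het %>%
    dplyr::left_join(fis[, c("locus", "F_IS")], by = "locus") %>%
    dplyr::left_join(hwe[, c("locus", "p_value")], by = "locus") %>%
    dplyr::rename(hwe_p = "p_value") %>%
    dplyr::mutate(f_null = null_allele_freq(.data$H_E, .data$H_O))
}
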