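#' Exact Hardy-Weinberg test for one locus
#'
#' The conditional "probability test": given the observed allele counts, the
#' probability of a genotype array under Hardy-Weinberg equilibrium is the
#' Levene/Haldane distribution
#' `Pr = n! * prod(m_i!) * 2^h / ((2n)! * prod(n_ij!))`
#' with `n` individuals, allele counts `m_i`, genotype counts `n_ij` and `h`
#' heterozygotes. The p-value sums `Pr` over all arrays no more probable
#' than the observed one. Arrays are enumerated exhaustively while their
#' number stays below `max_tables`; otherwise the test switches to
#' Monte-Carlo shuffling of gene copies and reports the standard error of
#' the estimate.
#'
#' @param a1,a2 Allele vectors of the typed individuals (one entry per
#'   individual; missing genotypes removed beforehand).
#' @param method `"auto"` (default), `"enumeration"` or `"monte_carlo"`.
#' @param max_tables Enumeration bound on the number of genotype arrays.
#' @param B Monte-Carlo sample size.
#' @param seed Optional seed making the Monte-Carlo path reproducible
#'   without touching the caller's RNG stream.
#' @return A list with `p_value`, `se` (`NA` for enumeration), `method`
#'   (`"enumeration"`, `"monte_carlo"` or `"none"`), `testable` (FALSE for a
#'   monomorphic locus, where `p_value = 1`), and `n_tables` (arrays
#'   enumerated, if applicable).
#' @seealso [hwe_test()] for the per-locus data-frame interface.
#' @export
#' @examples
#' hwe_exact_test(c(1, 1, 2, 2, 1), c(1, 2, 2, 2, 2))
hwe_exact_test <- function(a1, a2, method = c("auto", "enumeration", "monte_carlo"),
                           max_tables = 1e6, B = 1e5, seed = NULL) {
  method <- match.arg(method)
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]
  a2 <- a2[keep]
  n <- length(a1)
  if (n == 0) abort("no typed genotypes")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 1) {
    return(list(p_value = 1, se = NA_real_, method = "none", testable = FALSE, n_tables = 1L))
  }
  i <- match(a1, alleles)
  j <- match(a2, alleles)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  obs <- matrix(0L, k, k)
  for (r in seq_len(n)) obs[lo[r], hi[r]] <- obs[lo[r], hi[r]] + 1L
  m <- tabulate(c(lo, hi), k) # allele counts (2n total)

  log_var <- function(tab_upper, h) h * log(2) - sum(lgamma(tab_upper + 1))
  h_obs <- n - sum(diag(obs))
  obs_lv <- log_var(obs[upper.tri(obs, diag = TRUE)], h_obs)
  tol <- 1e-9

  # with many individuals *and* many alleles the array space is hopeless;
  # skip straight to Monte-Carlo instead of burning the enumeration budget
  hopeless <- n > 30 && k > 5
  if (method == "enumeration" || (method == "auto" && !hopeless)) {
    enum <- hwe_enumerate(m, n, obs_lv + tol, max_tables)
    if (!is.null(enum)) {
      return(list(
        p_value = enum$p, se = NA_real_, method = "enumeration",
        testable = TRUE, n_tables = enum$n_tables
      ))
    }
    if (method == "enumeration") {
      abort(sprintf("enumeration exceeds max_tables = %g; use the Monte-Carlo method", max_tables))
    }
  }

  # Monte-Carlo: random pairing of the 2n gene copies
  copies <- rep.int(seq_len(k), m)
  odd <- seq(1L, 2L * n, by = 2L)
  even <- odd + 1L
  le <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      g <- copies[sample.int(2L * n)]
      a <- g[odd]
      bb <- g[even]
      ii <- pmin(a, bb)
      jj <- pmax(a, bb)
      tab <- tabulate((ii - 1L) * k + jj, k * k)
      nz <- tab[tab > 1L]
      lv <- sum(a != bb) * log(2) - sum(lgamma(nz + 1))
      lv <= obs_lv + tol
    }, logical(1))
  })
  p <- mean(le)
  list(
    p_value = p, se = sqrt(p * (1 - p) / B), method = "monte_carlo",
    testable = TRUE, n_tables = NA_integer_
  )
}

# Exhaustive enumeration of genotype arrays with fixed allele counts.
# Returns NULL if the search would visit more than max_tables nodes
# (each complete array is at least one node, so this also bounds arrays).
hwe_enumerate <- function(m, n, obs_cut, max_tables) {
  k <- length(m)
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  n_cells <- nrow(cells)
  state <- new.env(parent = emptyenv())
  state$p <- 0
  state$total <- 0
  state$n_tables <- 0L
  state$overflow <- FALSE
  log_const <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1)

  state$nodes <- 0L

  recurse <- function(idx, rem, lsum, h) {
    if (state$overflow) {
      return()
    }
    state$nodes <- state$nodes + 1L
    if (state$nodes > max_tables) {
      state$overflow <- TRUE
      return()
    }
    if (idx > n_cells) {
      # all copies must be consumed (guaranteed by the per-row closing rules)
      state$n_tables <- state$n_tables + 1L
      lv <- h * log(2) - lsum
      pr <- exp(log_const + lv)
      state$total <- state$total + pr
      if (lv <= obs_cut) state$p <- state$p + pr
      return()
    }
    i <- cells[idx, 1]
    j <- cells[idx, 2]
    last_of_row <- (j == k)
    if (i == j) {
      cmax <- rem[i] %/% 2L
      cset <- if (last_of_row) {
        if (rem[i] %% 2L == 0L) rem[i] %/% 2L else integer(0)
      } else {
        0:cmax
      }
      for (c in cset) {
        rem2 <- rem
        rem2[i] <- rem2[i] - 2L * c
        recurse(idx + 1L, rem2, lsum + lgamma(c + 1), h)
      }
    } else {
      cmax <- min(rem[i], rem[j])
      cset <- if (last_of_row) {
        if (rem[i] <= rem[j]) rem[i] else integer(0)
      } else {
        0:cmax
      }
      for (c in cset) {
        rem2 <- rem
        rem2[i] <- rem2[i] - c
        rem2[j] <- rem2[j] - c
        recurse(idx + 1L, rem2, lsum + lgamma(c + 1), h + c)
      }
    }
  }
  recurse(1L, as.integer(m), 0, 0L)
  if (state$overflow) {
    return(NULL)
  }
  # guard against degenerate accumulation error
  list(p = min(1, state$p / state$total), n_tables = state$n_tables)
}

#' Hardy-Weinberg exact tests across loci
#'
#' Runs [hwe_exact_test()] on every locus of a dataset and returns a tidy
#' table. Monomorphic loci are reported with `p_value = 1` and
#' `testable = FALSE` rather than dropped.
#'
#' @inheritParams allele_frequencies
#' @inheritParams hwe_exact_test
#' @return A tibble with `locus`, `n`, `k` (alleles), `p_value`, `se`,
#'   `method`, `testable`.
#' @export
#' @examples
#' hwe_test(robin_families(), unrelated_only = TRUE)
hwe_test <- function(x, method = "auto", max_tables = 1e6, B = 1e5,
                     seed = NULL, unrelated_only = FALSE) {
  g <- msat_genotypes(x, unrelated_only = unrelated_only) %>%
    dplyr::filter(!is.na(.data$allele_1))
  g %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_modify(function(d, key) {
      res <- hwe_exact_test(d$allele_1, d$allele_2,
        method = method,
        max_tables = max_tables, B = B, seed = seed
      )
      tibble::tibble(
        n = nrow(d), k = length(unique(c(d$allele_1, d$allele_2))),
        p_value = res$p_value, se = res$se, method = res$method,
        testable = res$testable
      )
    }) %>%
    dplyr::ungroup()
}
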