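# Weir & Cockerham (1984) variance components per locus and allele.
# Returns a tibble with one row per locus x allele carrying components
# a (among populations), b (among individuals within populations) and
# c (within individuals). With a single population a is 0 by construction
# and only b and c (hence f = F_IS) are meaningful.
wc_components <- function(x, by = NULL, unrelated_only = FALSE) {
  g <- msat_genotypes(x, unrelated_only = unrelated_only) %>%
    dplyr::filter(!is.na(.data$allele_1))
  if (is.null(by)) {
    g$.pop <- "all"
  } else {
    g$.pop <- g[[by]]
  }
  g %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_modify(function(d, key) {
      pops <- factor(d$.pop)
      r <- nlevels(pops)
      ni <- as.vector(table(pops))
      nbar <- mean(ni)
      nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
      al <- factor(c(d$allele_1, d$allele_2))
      cnt <- unclass(table(rep(pops, 2), al)) # r x A allele counts
      p_mat <- cnt / (2 * ni)
      het <- d$allele_1 != d$allele_2
      hcnt <- unclass(table(pops[het], factor(d$allele_1[het], levels = levels(al)))) +
        unclass(table(pops[het], factor(d$allele_2[het], levels = levels(al))))
      h_mat <- hcnt / ni
      pbar <- colSums(ni * p_mat) / (r * nbar)
      hbar <- colSums(ni * h_mat) / (r * nbar)
      s2 <- if (r > 1) {
        colSums(ni * sweep(p_mat, 2, pbar)^2) / ((r - 1) * nbar)
      } else {
        rep(0, ncol(p_mat))
      }
      inner <- pbar * (1 - pbar) - (r - 1) / r * s2
      a <- if (r > 1) nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1)) else rep(0, ncol(p_mat))
      b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
      tibble::tibble(
        allele = as.numeric(levels(al)), a = a, b = b, c = hbar / 2
      )
    }) %>%
    dplyr::ungroup()
}

#' Weir-Cockerham fixation index F_IS
#'
#' The within-population inbreeding coefficient f of Weir & Cockerham
#' (1984), estimated from variance components that are summed over alleles
#' (and, for the overall value, over loci) before forming the ratio
#' `f = 1 - sum(c) / sum(b + c)`. Positive values indicate heterozygote
#' deficiency. Loci with an undefined ratio (zero denominator, e.g.
#' monomorphic) are reported `NA`.
#'
#' @inheritParams allele_frequencies
#' @param by Optional population column; with several populations the
#'   components are computed within populations and pooled.
#' @param n_perm If positive, a one-sided permutation test of heterozygote
#'   deficiency (gene copies shuffled among the individuals of each
#'   population) is run per locus; `p_value` is the fraction of
#'   permutations with f at least as large as observed.
#' @param seed Seed for the permutation test.
#' @return A tibble with `locus`, `F_IS` (and `p_value` when `n_perm > 0`),
#'   plus an overall row `locus = "(all)"` combining components across loci.
#' @export
fis_wc <- function(x, by = NULL, unrelated_only = FALSE, n_perm = 0, seed = NULL) {
  comp <- wc_components(x, by = by, unrelated_only = unrelated_only)
  per_locus <- comp %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(F_IS = fratio(1 - sum(.data$c) / sum(.data$b + .data$c),
      sum(.data$b + .data$c)
    ), .groups = "drop")
  overall <- tibble::tibble(
    locus = "(all)",
    F_IS = fratio(1 - sum(comp$c) / sum(comp$b + comp$c), sum(comp$b + comp$c))
  )
  out <- dplyr::bind_rows(per_locus, overall)
  if (n_perm > 0) {
    obs <- out$F_IS
    exceed <- rep(0, nrow(out))
    g0 <- msat_genotypes(x, unrelated_only = unrelated_only)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        gp <- permute_gene_copies(g0, by = by)
        fp <- fis_wc(gp, by = by, n_perm = 0)
        exceed <- exceed + (fp$F_IS[match(out$locus, fp$locus)] >= obs - 1e-12)
      }
    })
    out$p_value <- exceed / n_perm
  }
  out
}

fratio <- function(val, denom) if (!is.finite(val) || abs(denom) < 1e-300) NA_real_ else val

# shuffle gene copies among individuals within each population (breaks the
# within-individual association, preserving allele counts)
permute_gene_copies <- function(g, by = NULL) {
  key <- if (is.null(by)) g$locus else paste(g$locus, g[[by]])
  split_idx <- split(seq_len(nrow(g)), key)
  for (idx in split_idx) {
    typed <- idx[!is.na(g$allele_1[idx])]
    copies <- c(g$allele_1[typed], g$allele_2[typed])
    copies <- copies[sample.int(length(copies))]
    n <- length(typed)
    g$allele_1[typed] <- pmin(copies[seq_len(n)], copies[n + seq_len(n)])
    g$allele_2[typed] <- pmax(copies[seq_len(n)], copies[n + seq_len(n)])
  }
  g
}

#' Weir-Cockerham F_ST between population samples
#'
#' Estimates theta of Weir & Cockerham (1984) from variance components
#' summed over alleles and loci before the ratio, with an optional
#' permutation test in which individuals are shuffled between populations.
#' The estimator may be slightly negative around zero differentiation.
#'
#' @inheritParams allele_frequencies
#' @param by Population column (default `"population"`); at least two
#'   non-empty populations are required.
#' @param n_perm Number of permutations for the significance test (0 = no
#'   test); `p_value` is the fraction of permuted theta at least as large
#'   as observed.
#' @param seed Seed for the permutation test.
#' @return An object of class `msat_fst` with per-locus components; see
#'   [tidy.msat_fst()] and [glance.msat_fst()].
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 6)
#' pair <- sample_population_pair(draw_allele_frequencies(cfg), 30, 30, fst = 0.1)
#' fst_wc(pair)
fst_wc <- function(x, by = "population", unrelated_only = FALSE,
                   n_perm = 0, seed = NULL) {
  g <- msat_genotypes(x, unrelated_only = unrelated_only)
  pops <- unique(g[[by]])
  if (length(pops) < 2) abort("F_ST needs at least two non-empty populations")
  comp <- wc_components(g, by = by)
  per_locus <- comp %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(
      a = sum(.data$a), b = sum(.data$b), c = sum(.data$c),
      theta = fratio(
        sum(.data$a) / sum(.data$a + .data$b + .data$c),
        sum(.data$a + .data$b + .data$c)
      ),
      .groups = "drop"
    )
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  p_value <- NA_real_
  if (n_perm > 0) {
    ids <- unique(g$id)
    labels <- g[[by]][match(ids, g$id)]
    exceed <- 0
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        gp <- g
        gp[[by]] <- sample(labels)[match(gp$id, ids)]
        cp <- wc_components(gp, by = by)
        tp <- sum(cp$a) / sum(cp$a + cp$b + cp$c)
        exceed <- exceed + (tp >= theta - 1e-12)
      }
    })
    p_value <- exceed / n_perm
  }
  structure(
    list(
      theta = theta, per_locus = per_locus, populations = pops,
      n_perm = n_perm, p_value = p_value
    ),
    class = "msat_fst"
  )
}

#' @export
print.msat_fst <- function(x, ...) {
  cat(sprintf(
    "<msat_fst> theta = %.4f over %d loci (%s)%s\n",
    x$theta, nrow(x$per_locus), paste(x$populations, collapse = " vs "),
    if (x$n_perm > 0) sprintf("; permutation p = %.4g (%d perms)", x$p_value, x$n_perm) else ""
  ))
  invisible(x)
}

#' Tidy per-locus F_ST components
#'
#' @param x An `msat_fst` object.
#' @param ... Unused.
#' @return A tibble with `locus`, variance components `a`, `b`, `c` and the
#'   per-locus `theta`.
#' @method tidy msat_fst
#' @export
tidy.msat_fst <- function(x, ...) x$per_locus

#' One-row summary of an F_ST fit
#'
#' @param x An `msat_fst` object.
#' @param ... Unused.
#' @return A tibble with `theta`, `n_loci`, `n_perm`, `p_value`.
#' @method glance msat_fst
#' @export
glance.msat_fst <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, n_loci = nrow(x$per_locus),
    n_perm = x$n_perm, p_value = x$p_value
  )
}
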