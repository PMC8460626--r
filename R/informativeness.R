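#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein's measure of
#' marker informativeness for linkage and parentage studies). Always at most
#' the expected heterozygosity computed from the same frequencies.
#'
#' @param p Numeric vector of allele frequencies at one locus (sums to 1).
#' @return PIC, a single number in \[0, 1).
#' @export
#' @examples
#' pic(c(0.5, 0.5)) # 0.375
pic <- function(p) {
  p <- check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Probability of identity for unrelated individuals and for siblings
#'
#' PI is the probability that two independent Hardy-Weinberg genotypes are
#' identical: `2 (sum p^2)^2 - sum p^4`. PI_sibs is the corresponding
#' probability for two full siblings:
#' `0.25 + 0.5 sum p^2 + 0.5 (sum p^2)^2 - 0.25 sum p^4`. `PI <= PI_sibs`
#' always; both equal 1 at a monomorphic locus.
#'
#' @inheritParams pic
#' @return A named numeric vector `c(PI = ..., PI_sibs = ...)`.
#' @export
#' @examples
#' prob_identity(c(0.5, 0.5))
prob_identity <- function(p) {
  p <- check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  c(
    PI = 2 * s2^2 - s4,
    PI_sibs = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  )
}

#' Average non-exclusion probability of a locus
#'
#' Probability that a random, unrelated candidate is *not* excluded from
#' parentage at one locus, computed by exact enumeration over the genotype
#' space under Hardy-Weinberg proportions and Mendelian transmission (the
#' candidate side of each scenario factorises, so the enumeration is over
#' parent/offspring configurations with exact allele-set probabilities for
#' the candidate):
#'
#' * `first_parent` (NE-1P): candidate as sole tested parent; excluded only
#'   if it shares no allele with a random offspring.
#' * `second_parent` (NE-2P): candidate as father when the true mother is
#'   known; excluded if no partition of the offspring's alleles is
#'   compatible with mother plus candidate.
#' * `parent_pair` (NE-PP): two random candidates tested jointly against a
#'   random offspring of a true pair.
#' * `identity` (NE-I) and `sib_identity` (NE-SI): probability that two
#'   unrelated individuals, or two full siblings, share a genotype --
#'   identical to [prob_identity()] under their usual names.
#'
#' The ordering `NE_PP <= NE_2P <= NE_1P` holds for every frequency table.
#'
#' @inheritParams pic
#' @param scenario One of `"first_parent"`, `"second_parent"`,
#'   `"parent_pair"`, `"identity"`, `"sib_identity"`.
#' @return A probability in (0, 1\]; 1 at a monomorphic locus.
#' @export
#' @examples
#' non_exclusion(c(0.4, 0.3, 0.2, 0.1), "second_parent")
non_exclusion <- function(p, scenario = c(
                            "first_parent", "second_parent",
                            "parent_pair", "identity", "sib_identity"
                          )) {
  scenario <- match.arg(scenario)
  p <- check_freqs(p)
  k <- length(p)
  if (scenario == "identity") {
    return(unname(prob_identity(p)["PI"]))
  }
  if (scenario == "sib_identity") {
    return(unname(prob_identity(p)["PI_sibs"]))
  }

  # ordered offspring genotypes (i, j) with HWE weight p_i p_j
  ij <- expand.grid(i = seq_len(k), j = seq_len(k))
  w <- p[ij$i] * p[ij$j]

  if (scenario == "first_parent") {
    # candidate shares at least one allele with offspring {i, j}
    p_share <- ifelse(ij$i == ij$j,
      1 - (1 - p[ij$i])^2,
      1 - (1 - p[ij$i] - p[ij$j])^2
    )
    return(sum(w * p_share))
  }

  if (scenario == "second_parent") {
    # enumerate mother (u, v), transmitted maternal allele, paternal allele f;
    # the candidate father must carry an allele of the paternal-consistent set
    grid <- expand.grid(u = seq_len(k), v = seq_len(k), f = seq_len(k))
    total <- 0
    for (pick in 1:2) {
      m <- if (pick == 1) grid$u else grid$v
      wgt <- p[grid$u] * p[grid$v] * 0.5 * p[grid$f]
      # paternal-consistent set S: always f; also m when f is carried by mother
      f_in_mother <- grid$f == grid$u | grid$f == grid$v
      pS <- p[grid$f] + ifelse(f_in_mother & m != grid$f, p[m], 0)
      total <- total + sum(wgt * (1 - (1 - pS)^2))
    }
    return(total)
  }

  # parent_pair: offspring of a true pair is HWE-distributed; candidates M, F
  # jointly compatible iff one offspring allele sits in each, in some order
  q <- 1 - (1 - p)^2 # P(random genotype carries allele x)
  het <- ij$i != ij$j
  both <- 2 * p[ij$i] * p[ij$j] # P({i, j} subset of one genotype), i != j
  p_pair <- ifelse(het,
    2 * q[ij$i] * q[ij$j] - both^2,
    q[ij$i]^2
  )
  sum(w * p_pair)
}

#' Per-locus marker informativeness table
#'
#' PIC, null-allele estimate, probabilities of identity and the three
#' non-exclusion probabilities for every locus, from the sample allele
#' frequencies of (by default) the flagged unrelated subset. `NE_I` and
#' `NE_SI` repeat `PI` and `PI_sibs` under their non-exclusion names, as in
#' standard parentage software output.
#'
#' @inheritParams allele_frequencies
#' @return A tibble with columns `locus`, `A`, `PIC`, `f_null`, `PI`,
#'   `PI_sibs`, `NE_1P`, `NE_2P`, `NE_PP`, `NE_I`, `NE_SI`.
#' @seealso [panel_overall()] for the multi-locus combination.
#' @export
#' @examples
#' marker_informativeness(robin_families())
marker_informativeness <- function(x, unrelated_only = TRUE) {
  freqs <- allele_frequencies(x, unrelated_only = unrelated_only)
  het <- heterozygosity(x, unrelated_only = unrelated_only)
  freqs %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(
      A = dplyr::n(),
      PIC = pic(.data$freq),
      PI = prob_identity(.data$freq)[["PI"]],
      PI_sibs = prob_identity(.data$freq)[["PI_sibs"]],
      NE_1P = non_exclusion(.data$freq, "first_parent"),
      NE_2P = non_exclusion(.data$freq, "second_parent"),
      NE_PP = non_exclusion(.data$freq, "parent_pair"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(NE_I = .data$PI, NE_SI = .data$PI_sibs) %>%
    dplyr::left_join(
      dplyr::transmute(het,
        locus = .data$locus,
        f_null = null_allele_freq(.data$H_E, .data$H_O)
      ),
      by = "locus"
    ) %>%
    dplyr::select(
      "locus", "A", "PIC", "f_null", "PI", "PI_sibs",
      "NE_1P", "NE_2P", "NE_PP", "NE_I", "NE_SI"
    )
}

#' Combine informativeness over a marker panel
#'
#' Multi-locus products of the identity and non-exclusion probabilities
#' under the assumption of independent loci, as printed in the "overall"
#' row of marker characterisation tables. PIC has no product-of-probability
#' interpretation; both common conventions are reported, labelled as the
#' arithmetic mean and the product.
#'
#' @param info A per-locus table from [marker_informativeness()] (any subset
#'   of rows).
#' @return A one-row tibble with `n_loci`, `PIC_mean`, `PIC_product` and the
#'   products `PI`, `PI_sibs`, `NE_1P`, `NE_2P`, `NE_PP`, `NE_I`, `NE_SI`.
#'   Each product is no larger than the smallest per-locus value and is
#'   invariant to locus order.
#' @export
panel_overall <- function(info) {
  tibble::tibble(
    n_loci = nrow(info),
    PIC_mean = mean(info$PIC),
    PIC_product = prod(info$PIC),
    PI = prod(info$PI),
    PI_sibs = prod(info$PI_sibs),
    NE_1P = prod(info$NE_1P),
    NE_2P = prod(info$NE_2P),
    NE_PP = prod(info$NE_PP),
    NE_I = prod(info$NE_I),
    NE_SI = prod(info$NE_SI)
  )
}
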