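#' Mendelian trio check at one or more loci
#'
#' Tests whether an offspring genotype can arise from a mother and a social
#' father under Mendelian transmission, with the mother assumed to be the
#' true parent (nest-attending female). Verdicts per locus:
#'
#' * `compatible`: the offspring's alleles can be split so that one is
#'   carried by the mother and the other by the father.
#' * `mother_mismatch`: the offspring shares no allele with the mother.
#' * `father_mismatch`: some maternal assignment exists, but every one
#'   leaves a non-maternal allele that the father does not carry.
#' * `untestable`: any of the three genotypes is missing.
#'
#' The verdict is invariant to allele order within each genotype.
#'
#' @param offspring,mother,father Two-column matrices (or length-2 vectors)
#'   of allele sizes, one row per locus; `NA` marks a missing genotype.
#' @return A character vector of verdicts, one per locus.
#' @export
#' @examples
#' check_trio(c(140, 155), c(140, 155), c(137, 137)) # father_mismatch
check_trio <- function(offspring, mother, father) {
  as_mat <- function(g) {
    if (is.null(dim(g))) g <- matrix(g, ncol = 2, byrow = TRUE)
    g
  }
  o <- as_mat(offspring)
  m <- as_mat(mother)
  f <- as_mat(father)
  stopifnot(nrow(o) == nrow(m), nrow(o) == nrow(f))
  vapply(seq_len(nrow(o)), function(r) {
    if (anyNA(o[r, ]) || anyNA(m[r, ]) || anyNA(f[r, ])) {
      return("untestable")
    }
    o1 <- o[r, 1]
    o2 <- o[r, 2]
    in_m <- c(o1 %in% m[r, ], o2 %in% m[r, ])
    if (!any(in_m)) {
      return("mother_mismatch")
    }
    # paternal-consistent alleles: the partner of each maternally-carried allele
    S <- c(if (in_m[1]) o2, if (in_m[2]) o1)
    if (any(S %in% f[r, ])) "compatible" else "father_mismatch"
  }, character(1))
}

#' Exclusion-based parentage analysis of full families
#'
#' Runs [check_trio()] for every offspring of every family at every locus
#' and classifies each offspring:
#'
#' * `extra_pair`: at least `threshold` father-mismatch loci and at most one
#'   mother-mismatch locus -- the social father is excluded.
#' * `within_pair`: fully compatible at every testable locus.
#' * `unresolved`: one or more mismatches below the exclusion threshold
#'   (possible mutation, null allele or scoring artifact).
#'
#' Missing (untestable) loci count in neither numerator nor denominator.
#' Father mismatches in which the unexplained offspring allele is exactly
#' one repeat unit away from a paternal allele are additionally flagged
#' `near_miss` (single-step slippage candidates); the flag never changes a
#' verdict.
#'
#' @param x An [msat_data] object with families attached (or `families`
#'   supplied separately).
#' @param threshold Minimum number of father-mismatch loci required to
#'   declare extra-pair paternity (default 3; one or two mismatches are
#'   routinely tolerated as mutation or null-allele artifacts).
#' @param families Optional pedigree tibble overriding `x$families`.
#' @return An object of class `msat_parentage` with elements `verdicts`
#'   (per family x offspring x locus), `offspring` (per-offspring counts and
#'   classification), `families` (per-family EPP flag), `threshold`.
#'   See [tidy.msat_parentage()], [glance.msat_parentage()],
#'   [autoplot.msat_parentage()].
#' @export
#' @examples
#' fit <- parentage(robin_families())
#' tidy(fit)
#' glance(fit)
parentage <- function(x, threshold = 3, families = NULL) {
  fams <- if (!is.null(families)) {
    validate_pedigree(families, x$individuals$id)
  } else {
    x$families
  }
  if (nrow(fams) == 0) abort("no families to analyse")
  loci_tbl <- msat_loci(x)
  loci <- loci_tbl$locus
  motif <- if ("motif_length" %in% names(loci_tbl)) {
    loci_tbl$motif_length
  } else {
    rep(NA_integer_, length(loci))
  }

  geno_mat <- function(id) {
    g <- genotype_of(x, id)
    g <- g[match(loci, g$locus), ]
    cbind(g$allele_1, g$allele_2)
  }

  verdicts <- purrr::map_dfr(seq_len(nrow(fams)), function(r) {
    off <- geno_mat(fams$offspring[r])
    mom <- geno_mat(fams$mother[r])
    dad <- geno_mat(fams$father[r])
    v <- check_trio(off, mom, dad)
    near <- vapply(seq_along(loci), function(l) {
      if (v[l] != "father_mismatch" || is.na(motif[l])) {
        return(FALSE)
      }
      in_m <- c(off[l, 1] %in% mom[l, ], off[l, 2] %in% mom[l, ])
      S <- c(if (in_m[1]) off[l, 2], if (in_m[2]) off[l, 1])
      any(vapply(S, function(s) any(abs(s - dad[l, ]) == motif[l]), logical(1)))
    }, logical(1))
    tibble::tibble(
      family = fams$family[r], offspring = fams$offspring[r],
      locus = loci, verdict = v, near_miss = near
    )
  })

  offspring <- verdicts %>%
    dplyr::group_by(.data$family, .data$offspring) %>%
    dplyr::summarise(
      n_testable = sum(.data$verdict != "untestable"),
      n_compatible = sum(.data$verdict == "compatible"),
      n_father_mismatch = sum(.data$verdict == "father_mismatch"),
      n_mother_mismatch = sum(.data$verdict == "mother_mismatch"),
      n_near_miss = sum(.data$near_miss),
      .groups = "drop"
    ) %>%
    dplyr::mutate(classification = dplyr::case_when(
      .data$n_father_mismatch >= threshold & .data$n_mother_mismatch <= 1 ~ "extra_pair",
      .data$n_father_mismatch == 0 & .data$n_mother_mismatch == 0 ~ "within_pair",
      TRUE ~ "unresolved"
    ))
  # preserve pedigree row order
  offspring <- offspring[match(fams$offspring, offspring$offspring), ]

  fam_sum <- offspring %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(
      n_offspring = dplyr::n(),
      n_extra_pair = sum(.data$classification == "extra_pair"),
      epp = any(.data$classification == "extra_pair"),
      .groups = "drop"
    )

  structure(
    list(
      verdicts = verdicts, offspring = offspring, families = fam_sum,
      threshold = threshold
    ),
    class = "msat_parentage"
  )
}

#' @rdname parentage
#' @param family A single family id to analyse on its own.
#' @export
analyze_family <- function(x, family, threshold = 3) {
  fams <- x$families[x$families$family == family, ]
  if (nrow(fams) == 0) abort(paste0("unknown family: ", family))
  parentage(x, threshold = threshold, families = fams)
}

#' @export
print.msat_parentage <- function(x, ...) {
  s <- epp_summary(x)
  cat(sprintf(
    "<msat_parentage> %d families, %d offspring (threshold %d): %d extra-pair offspring in %d family/ies\n",
    s$n_families, s$n_offspring, x$threshold, s$n_extra_pair, s$n_epp_families
  ))
  print(x$offspring)
  invisible(x)
}

#' Per-offspring parentage classifications
#'
#' @param x An `msat_parentage` object.
#' @param ... Unused.
#' @return The per-offspring tibble: mismatch counts and classification.
#' @method tidy msat_parentage
#' @export
tidy.msat_parentage <- function(x, ...) x$offspring

#' One-row extra-pair paternity summary
#'
#' @param x An `msat_parentage` object.
#' @param ... Unused.
#' @return See [epp_summary()].
#' @method glance msat_parentage
#' @export
glance.msat_parentage <- function(x, ...) epp_summary(x)

#' Summarise extra-pair paternity rates
#'
#' @param x An `msat_parentage` object (or its per-offspring tibble).
#' @return A one-row tibble: `n_families`, `n_epp_families`, `family_rate`,
#'   `n_offspring`, `n_extra_pair`, `offspring_rate` (rates as fractions).
#' @export
#' @examples
#' epp_summary(parentage(robin_families()))
epp_summary <- function(x) {
  off <- if (inherits(x, "msat_parentage")) x$offspring else tibble::as_tibble(x)
  fam <- off %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(epp = any(.data$classification == "extra_pair"), .groups = "drop")
  tibble::tibble(
    n_families = nrow(fam),
    n_epp_families = sum(fam$epp),
    family_rate = sum(fam$epp) / nrow(fam),
    n_offspring = nrow(off),
    n_extra_pair = sum(off$classification == "extra_pair"),
    offspring_rate = sum(off$classification == "extra_pair") / nrow(off)
  )
}

#' Audit maternal-allele assignments within families
#'
#' For each offspring and locus, lists which offspring allele(s) can have
#' come from the mother. The assignment is `ambiguous` when the offspring is
#' heterozygous and both alleles occur in the mother. Loci where no
#' candidate paternal allele is carried by the social father are marked
#' `non_paternal`; these are exactly the loci [check_trio()] calls
#' `father_mismatch`.
#'
#' @inheritParams parentage
#' @return A tibble with `family`, `offspring`, `locus`,
#'   `maternal_options` (comma-separated allele sizes; `""` if none),
#'   `ambiguous`, `non_paternal`.
#' @export
maternal_audit <- function(x, families = NULL) {
  fams <- if (!is.null(families)) validate_pedigree(families, x$individuals$id) else x$families
  if (nrow(fams) == 0) abort("no families to audit")
  loci <- msat_loci(x)$locus
  purrr::map_dfr(seq_len(nrow(fams)), function(r) {
    og <- genotype_of(x, fams$offspring[r])
    mg <- genotype_of(x, fams$mother[r])
    fg <- genotype_of(x, fams$father[r])
    og <- og[match(loci, og$locus), ]
    mg <- mg[match(loci, mg$locus), ]
    fg <- fg[match(loci, fg$locus), ]
    purrr::map_dfr(seq_along(loci), function(l) {
      o <- c(og$allele_1[l], og$allele_2[l])
      m <- c(mg$allele_1[l], mg$allele_2[l])
      f <- c(fg$allele_1[l], fg$allele_2[l])
      if (anyNA(o) || anyNA(m)) {
        return(tibble::tibble(
          family = fams$family[r], offspring = fams$offspring[r], locus = loci[l],
          maternal_options = NA_character_, ambiguous = NA, non_paternal = NA
        ))
      }
      opts <- unique(o[o %in% m])
      S <- unique(c(if (o[1] %in% m) o[2], if (o[2] %in% m) o[1]))
      tibble::tibble(
        family = fams$family[r], offspring = fams$offspring[r], locus = loci[l],
        maternal_options = paste(opts, collapse = ","),
        ambiguous = o[1] != o[2] && all(o %in% m),
        non_paternal = if (anyNA(f)) NA else length(opts) > 0 && !any(S %in% f)
      )
    })
  })
}
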