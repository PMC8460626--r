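#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

#' Assemble a microsatellite genotype dataset
#'
#' The central container of the package: diploid genotypes scored as PCR
#' fragment sizes (bp, including the primer-flanked region), one unordered
#' allele pair per individual and locus, together with individual metadata,
#' locus definitions and (optionally) full-family pedigree records.
#'
#' @param genotypes A data frame in long form with columns `id`, `locus`,
#'   `allele_1`, `allele_2` (integer fragment sizes; both `NA` for a missing
#'   genotype) and optionally `population`, `role` (`"adult"` or
#'   `"nestling"`) and `unrelated` (logical; the explicit subset used for
#'   population statistics). Allele order within a genotype carries no
#'   meaning and is normalised so that `allele_1 <= allele_2`.
#' @param loci Optional locus definition table with columns `locus` and any
#'   of `motif_length` (3 or 4), `size_min`, `size_max`, `dye`, `mix`.
#'   Defaults to the loci present in `genotypes`.
#' @param families Optional pedigree as returned by [read_pedigree()]:
#'   columns `family`, `mother`, `father`, `offspring` (one row per
#'   offspring, row order preserved). All ids must resolve in `genotypes`.
#'
#' @details Genotypes whose alleles fall outside the locus size range are
#'   kept but reported with a warning: size ranges describe the span of
#'   fragments seen during marker characterisation, and off-ladder or
#'   out-of-range alleles are an expected feature of real fragment data.
#'   Missing individuals' metadata default to `population = "pop1"`,
#'   `role = "adult"`, and `unrelated = (role != "nestling")`.
#'
#' @return An object of class `msat_data`: a list with tibbles `genotypes`
#'   (long, one row per individual x locus), `individuals`, `loci` and
#'   `families`.
#' @seealso [read_genotype_table()], [robin_families()], [write_genepop()]
#' @export
#' @examples
#' geno <- tibble::tibble(
#'   id = rep(c("a", "b"), each = 2),
#'   locus = rep(c("L1", "L2"), 2),
#'   allele_1 = c(100L, 204L, 103L, 204L),
#'   allele_2 = c(103L, 208L, 103L, 212L)
#' )
#' msat_data(geno)
msat_data <- function(genotypes, loci = NULL, families = NULL) {
  genotypes <- tibble::as_tibble(genotypes)
  required <- c("id", "locus", "allele_1", "allele_2")
  miss <- setdiff(required, names(genotypes))
  if (length(miss) > 0) {
    abort(paste0("`genotypes` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(genotypes) == 0) abort("no individuals")

  if (!"population" %in% names(genotypes)) genotypes$population <- "pop1"
  if (!"role" %in% names(genotypes)) genotypes$role <- "adult"
  if (!"unrelated" %in% names(genotypes)) {
    genotypes$unrelated <- genotypes$role != "nestling"
  }

  genotypes <- genotypes %>%
    dplyr::mutate(
      allele_1 = as.integer(.data$allele_1),
      allele_2 = as.integer(.data$allele_2)
    )
  # half-missing genotypes are treated as fully missing
  half <- xor(is.na(genotypes$allele_1), is.na(genotypes$allele_2))
  if (any(half)) {
    warn(sprintf("%d genotype(s) with a single scored allele set to missing", sum(half)))
    genotypes$allele_1[half] <- NA_integer_
    genotypes$allele_2[half] <- NA_integer_
  }
  bad <- !is.na(genotypes$allele_1) & (genotypes$allele_1 <= 0 | genotypes$allele_2 <= 0)
  if (any(bad)) abort("allele sizes must be positive")
  # unordered-pair normalisation
  a <- pmin(genotypes$allele_1, genotypes$allele_2)
  b <- pmax(genotypes$allele_1, genotypes$allele_2)
  genotypes$allele_1 <- a
  genotypes$allele_2 <- b

  individuals <- genotypes %>%
    dplyr::distinct(.data$id, .data$population, .data$role, .data$unrelated)
  if (anyDuplicated(individuals$id) > 0) {
    abort(paste0(
      "duplicate individual id(s): ",
      paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", ")
    ))
  }

  if (is.null(loci)) {
    loci <- tibble::tibble(locus = unique(genotypes$locus))
  } else {
    loci <- tibble::as_tibble(loci)
    if (!"locus" %in% names(loci)) abort("`loci` needs a `locus` column")
    extra <- setdiff(unique(genotypes$locus), loci$locus)
    if (length(extra) > 0) {
      abort(paste0("genotypes carry loci absent from `loci`: ", paste(extra, collapse = ", ")))
    }
  }

  # every individual must be typed (possibly missing) at exactly the panel loci
  tab <- table(genotypes$id, factor(genotypes$locus, levels = loci$locus))
  if (any(tab != 1)) {
    off <- rownames(tab)[apply(tab != 1, 1, any)]
    abort(paste0("genotypes not keyed by the panel loci for: ", paste(off, collapse = ", ")))
  }

  if (all(c("size_min", "size_max") %in% names(loci))) {
    chk <- genotypes %>%
      dplyr::left_join(loci[, c("locus", "size_min", "size_max")], by = "locus") %>%
      dplyr::filter(
        !is.na(.data$allele_1) & !is.na(.data$size_min) &
          (.data$allele_1 < .data$size_min | .data$allele_2 > .data$size_max)
      )
    if (nrow(chk) > 0) {
      warn(sprintf(
        "%d genotype(s) outside the declared locus size range (kept): e.g. %s %s/%s at %s",
        nrow(chk), chk$id[1], chk$allele_1[1], chk$allele_2[1], chk$locus[1]
      ))
    }
  }

  if (is.null(families)) {
    families <- tibble::tibble(
      family = character(), mother = character(),
      father = character(), offspring = character()
    )
  } else {
    families <- validate_pedigree(tibble::as_tibble(families), individuals$id)
  }

  structure(
    list(
      genotypes = genotypes[, c("id", "locus", "allele_1", "allele_2")],
      individuals = individuals,
      loci = loci,
      families = families
    ),
    class = "msat_data"
  )
}

#' @export
print.msat_data <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes$allele_1))
  cat(sprintf(
    "<msat_data> %d individuals x %d loci (%d populations, %d families, %d missing genotypes)\n",
    nrow(x$individuals), nrow(x$loci),
    dplyr::n_distinct(x$individuals$population), dplyr::n_distinct(x$families$family),
    n_miss
  ))
  print(utils::head(msat_genotypes(x), 6))
  invisible(x)
}

#' Long genotype table of a dataset
#'
#' Returns the genotypes joined with individual metadata, one row per
#' individual and locus. All statistics in the package start from this view,
#' so they also accept any data frame with the same columns in place of an
#' `msat_data` object.
#'
#' @param x An `msat_data` object or a data frame already in this layout.
#' @param unrelated_only If `TRUE`, restrict to individuals flagged as
#'   belonging to the "unrelated" analysis subset.
#' @return A tibble with columns `id`, `population`, `role`, `unrelated`,
#'   `locus`, `allele_1`, `allele_2`.
#' @export
msat_genotypes <- function(x, unrelated_only = FALSE) {
  if (inherits(x, "msat_data")) {
    out <- dplyr::left_join(x$genotypes, x$individuals, by = "id") %>%
      dplyr::select(
        "id", "population", "role", "unrelated",
        "locus", "allele_1", "allele_2"
      )
  } else {
    out <- tibble::as_tibble(x)
    need <- c("id", "locus", "allele_1", "allele_2")
    miss <- setdiff(need, names(out))
    if (length(miss) > 0) {
      abort(paste0("not an msat_data and lacking column(s): ", paste(miss, collapse = ", ")))
    }
    if (!"population" %in% names(out)) out$population <- "pop1"
    if (!"unrelated" %in% names(out)) out$unrelated <- TRUE
  }
  if (unrelated_only) out <- dplyr::filter(out, .data$unrelated)
  out
}

msat_loci <- function(x) {
  if (inherits(x, "msat_data")) x$loci else tibble::tibble(locus = unique(x$locus))
}

genotype_of <- function(x, id) {
  g <- x$genotypes[x$genotypes$id == id, , drop = FALSE]
  if (nrow(g) == 0) abort(paste0("individual not in dataset: ", id))
  g
}

#' The 14-locus European Robin marker panel
#'
#' Locus definitions for the three published multiplex sets (Mix 1-3)
#' developed for the European Robin: dye label, fragment size range of the
#' PCR product, and the repeat-unit length. Motif lengths are not printed in
#' the characterisation table and were inferred from the allele-size ladders
#' of the published family genotypes (all allele differences at a locus are
#' multiples of 3 or 4).
#'
#' @return A tibble with columns `locus`, `mix`, `dye`, `motif_length`,
#'   `size_min`, `size_max`.
#' @export
#' @examples
#' robin_panel()
robin_panel <- function() {
  readr::read_csv(
    system.file("extdata", "robin_loci.csv", package = "msatkin"),
    show_col_types = FALSE
  )
}

#' Published per-locus reference statistics for the robin panel
#'
#' Diversity and informativeness statistics reported for the 14-locus panel
#' as characterised on 69 unrelated European Robins (45 Poland, 24
#' Portugal). The genotypes behind these numbers are unpublished, so they
#' serve as context for comparison, not as values this package recomputes.
#'
#' @return A tibble, one row per locus.
#' @export
robin_reference <- function() {
  readr::read_csv(
    system.file("extdata", "robin_reference_stats.csv", package = "msatkin"),
    show_col_types = FALSE
  )
}

#' Published genotypes of three full European Robin families
#'
#' The complete 14-locus genotypes of three full families (MO6: parents and
#' 8 nestlings; WA6: parents and 5; WE8: parents and 7) transcribed from the
#' published family table, with the pedigree linking each nestling to its
#' mother and social father. Family WE8 contains the published case of
#' extra-pair paternity; the social male's ER25 genotype is missing (the
#' locus failed in that sample).
#'
#' @return An [msat_data] object with 26 individuals (6 parents, 20 nestlings), 14 loci, 3 families.
#' @export
#' @examples
#' fam <- robin_families()
#' parentage(fam)
robin_families <- function() {
  read_genotype_table(
    system.file("extdata", "table3_genotypes.csv", package = "msatkin"),
    loci = robin_panel(),
    pedigree = system.file("extdata", "table3_pedigree.csv", package = "msatkin")
  )
}
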