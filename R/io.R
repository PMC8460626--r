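#' Read a wide genotype table
#'
#' Reads a delimited file with one row per individual and two allele columns
#' per locus, named `<locus>_1` and `<locus>_2` (fragment sizes in bp).
#' Leading metadata columns: `id` (required), and optionally `population`,
#' `role`, `unrelated`.
#'
#' @param path Path to a CSV (default) or TSV file; the delimiter is taken
#'   from the file extension.
#' @param missing Sentinel coding a missing allele; default `"0"`, the
#'   Genepop convention.
#' @param loci Optional locus definition table (see [msat_data()]); locus
#'   names must cover the loci found in the header.
#' @param pedigree Optional path to a pedigree file read with
#'   [read_pedigree()] and attached to the dataset.
#'
#' @details Unparseable allele fields are set to missing with a warning;
#'   duplicate individual ids and rows with a deviating number of fields are
#'   errors naming the offender.
#'
#' @return An [msat_data] object.
#' @export
read_genotype_table <- function(path, missing = "0", loci = NULL, pedigree = NULL) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("malformed genotype table, first problem at row ", prob$row[1], ": ", prob$expected[1]))
  }
  if (!"id" %in% names(raw)) abort("genotype table needs an `id` column")
  if (nrow(raw) == 0) abort("no individuals")
  if (anyDuplicated(raw$id) > 0) {
    abort(paste0("duplicate individual id(s): ", paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  }

  allele_cols <- grep("_[12]$", names(raw), value = TRUE)
  locus_names <- unique(sub("_[12]$", "", allele_cols))
  incomplete <- locus_names[!(paste0(locus_names, "_1") %in% names(raw) &
    paste0(locus_names, "_2") %in% names(raw))]
  if (length(incomplete) > 0) {
    abort(paste0("locus column pair incomplete for: ", paste(incomplete, collapse = ", ")))
  }
  if (length(locus_names) == 0) abort("no locus columns (`<locus>_1`/`<locus>_2`) found")

  long <- raw %>%
    tidyr::pivot_longer(
      cols = dplyr::all_of(allele_cols),
      names_to = c("locus", ".value"),
      names_pattern = "(.*)_([12])$"
    ) %>%
    dplyr::rename(allele_1 = "1", allele_2 = "2")
  for (col in c("allele_1", "allele_2")) {
    v <- long[[col]]
    v[v %in% missing | v == ""] <- NA_character_
    parsed <- suppressWarnings(as.integer(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) {
      warn(sprintf(
        "%d unparseable allele field(s) set to missing (e.g. \"%s\" at %s, %s)",
        sum(bad), v[bad][1], long$id[bad][1], long$locus[bad][1]
      ))
    }
    long[[col]] <- parsed
  }
  if ("unrelated" %in% names(long)) long$unrelated <- as.logical(long$unrelated)

  fam <- if (!is.null(pedigree)) read_pedigree(pedigree) else NULL
  msat_data(long, loci = loci, families = fam)
}

#' Write a wide genotype table
#'
#' Inverse of [read_genotype_table()]: one row per individual, two columns
#' per locus. A write/read round trip reproduces the genotypes exactly.
#'
#' @param x An [msat_data] object.
#' @param path Output path (`.csv` or `.tsv`).
#' @param missing Sentinel written for missing alleles (default `"0"`).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, missing = "0") {
  wide <- msat_genotypes(x) %>%
    dplyr::mutate(
      locus = factor(.data$locus, levels = msat_loci(x)$locus),
      allele_1 = ifelse(is.na(.data$allele_1), missing, as.character(.data$allele_1)),
      allele_2 = ifelse(is.na(.data$allele_2), missing, as.character(.data$allele_2))
    ) %>%
    dplyr::arrange(.data$locus) %>%
    tidyr::pivot_wider(
      names_from = "locus", values_from = c("allele_1", "allele_2"),
      names_glue = "{locus}_{ifelse(.value == 'allele_1', 1, 2)}"
    )
  ord <- as.vector(rbind(
    paste0(msat_loci(x)$locus, "_1"),
    paste0(msat_loci(x)$locus, "_2")
  ))
  wide <- wide[, c("id", "population", "role", "unrelated", ord)]
  if (grepl("\\.tsv$|\\.txt$", path)) {
    readr::write_tsv(wide, path)
  } else {
    readr::write_csv(wide, path)
  }
  invisible(path)
}

#' Read a pedigree of full families
#'
#' @param path Delimited file with columns `family`, `mother`, `father`,
#'   `offspring`, one offspring per row. Offspring of one family may be
#'   spread over several rows; their order is preserved.
#' @return A tibble with one row per offspring.
#' @export
read_pedigree <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  ped <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()), trim_ws = TRUE
  )
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped A pedigree data frame to validate.
#' @param ids Optional vector of individual ids; when given, every pedigree
#'   member must resolve against it.
#' @export
validate_pedigree <- function(ped, ids = NULL) {
  ped <- tibble::as_tibble(ped)
  need <- c("family", "mother", "father", "offspring")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) abort(paste0("pedigree lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(ped) == 0) {
    return(ped[, need])
  }
  if (anyDuplicated(ped$offspring) > 0) {
    abort(paste0(
      "offspring listed more than once: ",
      paste(unique(ped$offspring[duplicated(ped$offspring)]), collapse = ", ")
    ))
  }
  fam_par <- ped %>% dplyr::distinct(.data$family, .data$mother, .data$father)
  if (anyDuplicated(fam_par$family) > 0) {
    abort("a family must have a single mother and social father")
  }
  if (any(fam_par$mother == fam_par$father)) {
    abort("mother and social father must differ")
  }
  if (!is.null(ids)) {
    members <- unique(c(ped$mother, ped$father, ped$offspring))
    unknown <- setdiff(members, ids)
    if (length(unknown) > 0) {
      abort(paste0("pedigree member(s) not in dataset: ", paste(unknown, collapse = ", ")))
    }
  }
  ped[, need]
}

#' @rdname read_pedigree
#' @return For `write_pedigree()`, `path` invisibly.
#' @export
write_pedigree <- function(ped, path) {
  if (grepl("\\.tsv$|\\.txt$", path)) {
    readr::write_tsv(ped, path)
  } else {
    readr::write_csv(ped, path)
  }
  invisible(path)
}

#' Export a dataset in Genepop format
#'
#' Writes the standard Genepop dialect: a title line, one locus name per
#' line, then one `Pop` block per population with individuals coded as
#' three-digit allele pairs (missing = `000`). This enables cross-checks
#' against the Genepop program family, which was used for the published
#' Hardy-Weinberg tests.
#'
#' @param x An [msat_data] object. All allele sizes must be at most 999 bp
#'   (three-digit coding); larger sizes are an error asking for a recode.
#' @param path Output path (conventionally `.gen`).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "msatkin export") {
  g <- msat_genotypes(x)
  if (any(g$allele_2 > 999, na.rm = TRUE)) {
    abort("allele size > 999 cannot be Genepop 3-digit coded; recode alleles first")
  }
  loci <- msat_loci(x)$locus
  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  lines <- c(title, loci)
  for (pop in unique(g$population)) {
    lines <- c(lines, "Pop")
    gp <- g[g$population == pop, ]
    for (ind in unique(gp$id)) {
      gi <- gp[gp$id == ind, ]
      gi <- gi[match(loci, gi$locus), ]
      lines <- c(lines, paste0(
        ind, " ,  ",
        paste0(code(gi$allele_1), code(gi$allele_2), collapse = " ")
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readDNAStringSet()` returning a named
#' character vector, the form the repeat scanner consumes.
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}
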