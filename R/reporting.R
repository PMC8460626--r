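#' Render report tables
#'
#' Formatting helpers mirroring the layout of marker characterisation
#' papers: numeric columns rounded to three decimals, panel-combination
#' probabilities in scientific notation. Full precision is preserved by
#' writing a parallel JSON file when a report is saved.
#'
#' @param x A tibble of per-locus statistics.
#' @param digits Decimal places (default 3).
#' @return A tibble of formatted strings.
#' @export
format_report <- function(x, digits = 3) {
  dplyr::mutate(x, dplyr::across(
    dplyr::where(is.numeric),
    function(v) {
      ifelse(is.na(v), "",
        ifelse(abs(v) > 0 & abs(v) < 10^(-digits),
          sprintf("%.3G", v), sprintf(paste0("%.", digits, "f"), v)
        )
      )
    }
  ))
}

write_report <- function(tbl, path, seed = NULL, config = NULL) {
  # no timestamp: identical invocation and seed must give identical bytes
  header <- c(
    sprintf("# msatkin %s", as.character(utils::packageVersion("msatkin"))),
    if (!is.null(seed)) sprintf("# seed %s", seed),
    if (!is.null(config)) sprintf("# options %s", config)
  )
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  readr::write_tsv(format_report(tbl), path, append = TRUE, col_names = TRUE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(tbl, sub("\\.tsv$", ".json", path),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Command-line entry point
#'
#' Backs the `msatkin` script shipped in `inst/exec/`: subcommands `stats`,
#' `parentage`, `simulate` and `discover`, writing TSV reports (with a
#' provenance header recording version, seed and options) plus
#' full-precision JSON siblings into `--out`. Identical invocations with
#' the same seed produce byte-identical report bodies.
#'
#' @param args Character vector of command-line arguments (default: the
#'   live command line).
#' @return Exit status, invisibly (0 on success).
#' @export
run_msatkin <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: msatkin <stats|parentage|simulate|discover> [options]",
    "  stats      --genotypes FILE [--pedigree FILE] [--unrelated-only]",
    "             [--rarefy G] [--hwe-mc B] [--seed S] [--out DIR]",
    "  parentage  --genotypes FILE --pedigree FILE [--threshold 3] [--out DIR]",
    "  simulate   --seed S [--families N] [--loci N] [--out DIR]",
    "  discover   --fasta FILE [--min-repeats 5] [--motif-lengths 3,4] [--out DIR]",
    sep = "\n"
  )
  if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    message("msatkin ", as.character(utils::packageVersion("msatkin")))
    return(invisible(0L))
  }
  sub <- args[1]
  if (!sub %in% c("stats", "parentage", "simulate", "discover")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the command-line interface needs the optparse package")
    return(invisible(2L))
  }
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--genotypes", type = "character"),
      optparse::make_option("--pedigree", type = "character"),
      optparse::make_option("--fasta", type = "character"),
      optparse::make_option("--out", type = "character", default = "."),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--threshold", type = "integer", default = 3L),
      optparse::make_option("--rarefy", type = "integer", default = NA_integer_),
      optparse::make_option("--hwe-mc", type = "integer", default = 100000L, dest = "hwe_mc"),
      optparse::make_option("--min-repeats", type = "integer", default = 5L, dest = "min_repeats"),
      optparse::make_option("--motif-lengths",
        type = "character", default = "3,4",
        dest = "motif_lengths"
      ),
      optparse::make_option("--families", type = "integer", default = 7L),
      optparse::make_option("--loci", type = "integer", default = 14L),
      optparse::make_option("--unrelated-only",
        action = "store_true", default = FALSE,
        dest = "unrelated_only"
      )
    )),
    args = args[-1]
  )
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  echo <- paste(args, collapse = " ")

  status <- tryCatch(
    {
      switch(sub,
        stats = {
          x <- read_genotype_table(opts$genotypes, pedigree = opts$pedigree)
          div <- locus_diversity(x,
            unrelated_only = opts$unrelated_only,
            hwe_args = list(B = opts$hwe_mc, seed = opts$seed)
          )
          write_report(div, file.path(opts$out, "diversity.tsv"),
            seed = opts$seed, config = echo
          )
          info <- marker_informativeness(x, unrelated_only = opts$unrelated_only)
          write_report(
            dplyr::bind_rows(
              info,
              dplyr::mutate(panel_overall(info), locus = "Overall", PIC = .data$PIC_mean)
            ),
            file.path(opts$out, "informativeness.tsv"),
            seed = opts$seed, config = echo
          )
          pops <- unique(x$individuals$population)
          if (length(pops) > 1) {
            g <- if (is.na(opts$rarefy)) NULL else opts$rarefy
            write_report(allelic_richness(x, g = g),
              file.path(opts$out, "richness.tsv"),
              seed = opts$seed, config = echo
            )
            fst <- fst_wc(x, n_perm = 1000, seed = opts$seed)
            write_report(glance(fst), file.path(opts$out, "fst.tsv"),
              seed = opts$seed, config = echo
            )
          }
          message("stats written to ", opts$out)
          0L
        },
        parentage = {
          x <- read_genotype_table(opts$genotypes, pedigree = opts$pedigree)
          fit <- parentage(x, threshold = opts$threshold)
          write_report(fit$offspring, file.path(opts$out, "parentage_offspring.tsv"),
            seed = opts$seed, config = echo
          )
          write_report(epp_summary(fit), file.path(opts$out, "parentage_summary.tsv"),
            seed = opts$seed, config = echo
          )
          message("parentage report written to ", opts$out)
          0L
        },
        simulate = {
          cfg <- sim_config(
            seed = opts$seed, n_loci = opts$loci,
            n_families = opts$families
          )
          sim <- simulate_dataset(cfg)
          write_genotype_table(sim$data, file.path(opts$out, "genotypes.csv"))
          write_pedigree(sim$data$families, file.path(opts$out, "pedigree.csv"))
          readr::write_csv(sim$truth$offspring, file.path(opts$out, "truth_offspring.csv"))
          readr::write_csv(sim$freqs, file.path(opts$out, "allele_frequencies.csv"))
          message("simulated dataset (seed ", opts$seed, ") written to ", opts$out)
          0L
        },
        discover = {
          seqs <- read_fasta(opts$fasta)
          ml <- as.integer(strsplit(opts$motif_lengths, ",")[[1]])
          cand <- find_ssrs(seqs, min_repeats = opts$min_repeats, motif_lengths = ml)
          screened <- group_for_multiplex(screen_candidates(cand, seqs))
          write_report(screened, file.path(opts$out, "candidates.tsv"),
            seed = opts$seed, config = echo
          )
          message(
            sum(screened$pass), " of ", nrow(screened),
            " candidates pass; report written to ", opts$out
          )
          0L
        }
      )
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
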