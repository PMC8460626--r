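#' Simulation configuration
#'
#' Bundles and validates the parameters of the genotype/pedigree/sequence
#' simulator. The defaults emulate the design of the robin marker study:
#' a 14-locus tri-/tetra-nucleotide panel with 9-26 alleles per locus,
#' two populations of 45 and 24 unrelated individuals differentiated at
#' F_ST = 0.015, and 7 full families of 4-8 nestlings with a family-level
#' extra-pair paternity rate of 1/7 (about 0.3 of the brood sired by the
#' extra male when it occurs).
#'
#' @param seed Integer seed; mandatory provenance of every simulated
#'   dataset.
#' @param n_loci Number of loci.
#' @param allele_range Range of allele counts per locus (drawn uniformly).
#' @param concentration Dirichlet concentration of the allele-frequency
#'   draw; 1 gives flat-Dirichlet (uneven, realistic) spectra, large values
#'   approach equifrequent alleles.
#' @param motif_lengths Candidate repeat-unit lengths (3 and/or 4).
#' @param size_ranges Optional tibble `locus`, `motif_length`, `size_min`,
#'   `size_max` fixing the allele ladders (e.g. [robin_panel()]); an error
#'   is raised if a drawn allele count cannot fit the ladder. Default
#'   `NULL`: ladders are synthesised wide enough for the drawn counts,
#'   with off-step gaps, within 90-450 bp.
#' @param n_populations,pop_sizes,fst Population structure of the
#'   "unrelated" sample: sizes per population and the Balding-Nichols
#'   differentiation parameter.
#' @param f Within-population inbreeding coefficient used by
#'   [sample_population()].
#' @param n_families,offspring_range Number of full families and the range
#'   of brood sizes.
#' @param epp_rate Probability that a family contains extra-pair young.
#' @param epp_nestling_fraction Expected fraction of the brood sired by the
#'   extra-pair male in such a family (at least one nestling is always
#'   extra-pair in a flagged family).
#' @param null_allele_freq Per-locus frequency of a non-amplifying allele.
#' @param genotyping_error Per-allele probability of a scoring error (the
#'   allele is moved one motif step up or down).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, n_loci = 14, allele_range = c(9, 26),
                       concentration = 1, motif_lengths = c(3, 4),
                       size_ranges = NULL, n_populations = 2,
                       pop_sizes = c(45, 24), fst = 0.015, f = 0,
                       n_families = 7, offspring_range = c(4, 8),
                       epp_rate = 1 / 7, epp_nestling_fraction = 0.3,
                       null_allele_freq = 0, genotyping_error = 0) {
  cfg <- list(
    seed = seed, n_loci = n_loci, allele_range = allele_range,
    concentration = concentration, motif_lengths = motif_lengths,
    size_ranges = size_ranges, n_populations = n_populations,
    pop_sizes = pop_sizes, fst = fst, f = f,
    n_families = n_families, offspring_range = offspring_range,
    epp_rate = epp_rate, epp_nestling_fraction = epp_nestling_fraction,
    null_allele_freq = null_allele_freq, genotyping_error = genotyping_error
  )
  rates <- c(cfg$fst, cfg$f, cfg$epp_rate, cfg$epp_nestling_fraction,
             cfg$null_allele_freq, cfg$genotyping_error)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (cfg$fst >= 1) abort("fst must be below 1")
  stopifnot(
    cfg$n_loci >= 1, cfg$allele_range[1] >= 1,
    cfg$allele_range[2] >= cfg$allele_range[1],
    all(cfg$motif_lengths %in% c(3, 4)), cfg$concentration > 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Draw per-locus allele frequency tables
#'
#' Allele counts are uniform over the configured range; allele sizes sit on
#' the motif ladder within the locus size range (a random subset of ladder
#' steps, so gaps occur as in real panels); frequencies are
#' Dirichlet-distributed with the configured concentration.
#'
#' @param config A [sim_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A tibble with `locus`, `motif_length`, `allele`, `freq`
#'   (summing to 1 within each locus), usable wherever sample frequencies
#'   are (e.g. [pic()], [non_exclusion()], the samplers below).
#' @export
draw_allele_frequencies <- function(config = sim_config(), seed = config$seed) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(config$n_loci), function(l) {
      A <- sample_range(config$allele_range[1], config$allele_range[2])
      if (!is.null(config$size_ranges)) {
        sr <- config$size_ranges[((l - 1) %% nrow(config$size_ranges)) + 1, ]
        motif <- sr$motif_length
        ladder <- seq(sr$size_min, sr$size_max, by = motif)
        if (length(ladder) < A) {
          abort(sprintf(
            "size range %d-%d cannot hold %d alleles on a %d bp ladder",
            sr$size_min, sr$size_max, A, motif
          ))
        }
      } else {
        motif <- sample(config$motif_lengths, 1)
        lo <- sample_range(90L, 300L)
        ladder <- seq(lo, lo + motif * (A + 10), by = motif)
      }
      sizes <- sort(sample(ladder, A))
      w <- stats::rgamma(A, shape = config$concentration)
      tibble::tibble(
        locus = sprintf("L%02d", l), motif_length = motif,
        allele = as.integer(sizes), freq = w / sum(w)
      )
    })
  })
}

# Balding-Nichols draw of population-specific frequencies around
# ancestral frequencies p with differentiation parameter fst
bn_draw <- function(p, fst) {
  if (fst <= 0) {
    return(p)
  }
  w <- stats::rgamma(length(p), shape = p * (1 - fst) / fst)
  if (sum(w) == 0) p else w / sum(w)
}

# one locus draw of n diploid genotypes; with probability f the two gene
# copies are identical by descent
draw_genotypes <- function(alleles, p, n, f = 0) {
  a1 <- sample(alleles, n, replace = TRUE, prob = p)
  a2 <- sample(alleles, n, replace = TRUE, prob = p)
  if (f > 0) {
    ibd <- stats::runif(n) < f
    a2[ibd] <- a1[ibd]
  }
  cbind(pmin(a1, a2), pmax(a1, a2))
}

#' Sample a population under Hardy-Weinberg (optionally inbred)
#'
#' Each genotype draws two independent gene copies from the locus
#' frequencies; with probability `f` the second copy duplicates the first
#' (identity by descent), producing an expected fixation index of `f`.
#'
#' @param freqs A frequency table from [draw_allele_frequencies()] (columns
#'   `locus`, `allele`, `freq`).
#' @param n Number of diploid individuals.
#' @param f Inbreeding coefficient in \[0, 1\].
#' @param population,prefix Population label and id prefix.
#' @param seed Optional seed.
#' @return A long genotype tibble (see [msat_genotypes()]).
#' @export
sample_population <- function(freqs, n, f = 0, population = "pop1",
                              prefix = population, seed = NULL) {
  with_seed(seed, {
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    purrr::map_dfr(split(freqs, freqs$locus), function(fl) {
      g <- draw_genotypes(fl$allele, fl$freq, n, f)
      tibble::tibble(
        id = ids, population = population, role = "adult", unrelated = TRUE,
        locus = fl$locus[1], allele_1 = g[, 1], allele_2 = g[, 2]
      )
    }) %>% dplyr::arrange(match(.data$id, ids))
  })
}

#' Sample two differentiated populations (Balding-Nichols model)
#'
#' Population-specific allele frequencies are drawn from a Dirichlet with
#' parameters `p * (1 - F) / F` around the ancestral frequencies `p`
#' (the multi-allele Balding-Nichols model, giving expected Weir-Cockerham
#' differentiation close to `fst`), then each population is sampled under
#' Hardy-Weinberg.
#'
#' @inheritParams sample_population
#' @param n1,n2 Sample sizes of the two populations.
#' @param fst Target differentiation; 0 reuses the ancestral frequencies.
#' @param pop_names Labels of the two populations.
#' @return An [msat_data] object with two populations.
#' @export
sample_population_pair <- function(freqs, n1, n2, fst = 0.015,
                                   pop_names = c("popA", "popB"), seed = NULL) {
  with_seed(seed, {
    pops <- purrr::map2_dfr(c(n1, n2), pop_names, function(n, nm) {
      purrr::map_dfr(split(freqs, freqs$locus), function(fl) {
        g <- draw_genotypes(fl$allele, bn_draw(fl$freq, fst), n)
        tibble::tibble(
          id = sprintf("%s_%03d", nm, seq_len(n)), population = nm,
          role = "adult", unrelated = TRUE,
          locus = fl$locus[1], allele_1 = g[, 1], allele_2 = g[, 2]
        )
      })
    })
    loci <- dplyr::distinct(freqs[, c("locus", "motif_length")])
    msat_data(pops, loci = loci)
  })
}

#' Simulate full families with optional extra-pair paternity
#'
#' Parents are drawn under Hardy-Weinberg from the supplied frequencies.
#' Each family is flagged extra-pair with probability `epp_rate`; in a
#' flagged family a single extra-pair male is drawn and each nestling is
#' sired by him with probability `epp_nestling_fraction` (at least one
#' nestling always is, so the family-level flag is meaningful). Offspring
#' inherit one uniformly chosen allele from each true parent. Afterwards a
#' null allele (frequency `null_allele_freq`, making carriers appear
#' homozygous, and missing when homozygous null) and per-allele genotyping
#' errors (one motif step up or down) are applied to the *observed*
#' genotypes; the truth record keeps the transmission and every masking
#' event.
#'
#' @inheritParams sample_population
#' @param config A [sim_config()].
#' @return A list: `data` (an [msat_data] with parents, nestlings and
#'   pedigree; parents carry `unrelated = TRUE`, nestlings `FALSE`) and
#'   `truth` (list with `offspring` -- family, offspring id, `sire`
#'   (`"social"`/`"extra_pair"`), extra sire genotypes are included in
#'   neither dataset nor pedigree -- and `events`, one row per null-masking
#'   or scoring-error event).
#' @export
simulate_families <- function(freqs, config = sim_config(), seed = config$seed) {
  with_seed(seed, {
    loci_tbl <- split(freqs, freqs$locus)
    loci <- names(loci_tbl)
    null_f <- config$null_allele_freq
    NULL_ALLELE <- -1L

    draw_parent <- function() {
      vapply(loci_tbl, function(fl) {
        p <- fl$freq
        al <- fl$allele
        if (null_f > 0) {
          p <- c(p * (1 - null_f), null_f)
          al <- c(al, NULL_ALLELE)
        }
        sample(al, 2, replace = TRUE, prob = p)
      }, integer(2))
    }

    geno_rows <- list()
    ped <- list()
    truth_off <- list()
    events <- list()

    observe <- function(id, gmat) {
      # gmat: 2 x n_loci true genotypes (may carry the null allele code)
      purrr::map_dfr(seq_along(loci), function(l) {
        a <- gmat[, l]
        ev <- character(0)
        if (any(a == NULL_ALLELE)) {
          if (all(a == NULL_ALLELE)) {
            ev <- "null_dropout"
            a <- c(NA_integer_, NA_integer_)
          } else {
            ev <- "null_masked"
            a <- rep(a[a != NULL_ALLELE], 2)
          }
        } else if (config$genotyping_error > 0) {
          step <- freqs$motif_length[match(loci[l], freqs$locus)]
          err <- stats::runif(2) < config$genotyping_error
          if (any(err)) {
            ev <- "scoring_error"
            a[err] <- a[err] + sample(c(-step, step), sum(err), replace = TRUE)
          }
        }
        if (length(ev) > 0) {
          events[[length(events) + 1]] <<- tibble::tibble(id = id, locus = loci[l], event = ev)
        }
        tibble::tibble(
          id = id, locus = loci[l],
          allele_1 = as.integer(min(a)), allele_2 = as.integer(max(a))
        )
      })
    }

    for (fam_i in seq_len(config$n_families)) {
      fam <- sprintf("fam%02d", fam_i)
      mom_id <- paste0(fam, "_F")
      dad_id <- paste0(fam, "_M")
      mom <- draw_parent()
      dad <- draw_parent()
      epp_family <- stats::runif(1) < config$epp_rate
      extra <- if (epp_family) draw_parent() else NULL
      n_off <- sample_range(config$offspring_range[1], config$offspring_range[2])
      is_ep <- if (epp_family) {
        v <- stats::runif(n_off) < config$epp_nestling_fraction
        if (!any(v)) v[sample.int(n_off, 1)] <- TRUE
        v
      } else {
        rep(FALSE, n_off)
      }

      geno_rows[[length(geno_rows) + 1]] <- dplyr::mutate(
        observe(mom_id, mom), population = "families", role = "adult", unrelated = TRUE
      )
      geno_rows[[length(geno_rows) + 1]] <- dplyr::mutate(
        observe(dad_id, dad), population = "families", role = "adult", unrelated = TRUE
      )
      for (o in seq_len(n_off)) {
        off_id <- sprintf("%s_%d", fam, o)
        sire <- if (is_ep[o]) extra else dad
        gmat <- vapply(seq_along(loci), function(l) {
          c(mom[sample.int(2, 1), l], sire[sample.int(2, 1), l])
        }, integer(2))
        geno_rows[[length(geno_rows) + 1]] <- dplyr::mutate(
          observe(off_id, gmat), population = "families", role = "nestling", unrelated = FALSE
        )
        ped[[length(ped) + 1]] <- tibble::tibble(
          family = fam, mother = mom_id, father = dad_id, offspring = off_id
        )
        truth_off[[length(truth_off) + 1]] <- tibble::tibble(
          family = fam, offspring = off_id,
          sire = if (is_ep[o]) "extra_pair" else "social"
        )
      }
    }

    loci_def <- dplyr::distinct(freqs[, c("locus", "motif_length")])
    data <- msat_data(dplyr::bind_rows(geno_rows),
      loci = loci_def,
      families = dplyr::bind_rows(ped)
    )
    list(
      data = data,
      truth = list(
        offspring = dplyr::bind_rows(truth_off),
        events = if (length(events) > 0) dplyr::bind_rows(events) else
          tibble::tibble(id = character(), locus = character(), event = character())
      )
    )
  })
}

#' Simulate a complete study dataset
#'
#' Draws allele frequencies, samples the two "unrelated" population samples
#' at the configured differentiation, and adds the full families (bred from
#' the first population's frequencies). The combined dataset round-trips
#' through [write_genotype_table()]/[read_genotype_table()].
#'
#' @param config A [sim_config()].
#' @return A list: `data` ([msat_data]), `freqs` (ancestral frequency
#'   table), `truth` (see [simulate_families()]).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 42, n_loci = 4, n_families = 2))
#' sim$data
simulate_dataset <- function(config = sim_config()) {
  with_seed(config$seed, {
    freqs <- draw_allele_frequencies(config, seed = NULL)
    pops <- purrr::map2_dfr(
      config$pop_sizes, seq_along(config$pop_sizes),
      function(n, i) {
        nm <- sprintf("pop%d", i)
        purrr::map_dfr(split(freqs, freqs$locus), function(fl) {
          g <- draw_genotypes(fl$allele, bn_draw(fl$freq, config$fst), n, config$f)
          tibble::tibble(
            id = sprintf("%s_%03d", nm, seq_len(n)), population = nm,
            role = "adult", unrelated = TRUE,
            locus = fl$locus[1], allele_1 = g[, 1], allele_2 = g[, 2]
          )
        })
      }
    )
    fams <- simulate_families(freqs, config, seed = NULL)
    all_geno <- dplyr::bind_rows(pops, msat_genotypes(fams$data))
    data <- msat_data(all_geno,
      loci = dplyr::distinct(freqs[, c("locus", "motif_length")]),
      families = fams$data$families
    )
    list(data = data, freqs = freqs, truth = fams$truth)
  })
}

#' Generate sequences with planted tandem repeats
#'
#' Random background sequence of configurable GC content with
#' non-overlapping planted perfect repeats and a truth table listing every
#' plant. Backgrounds are redrawn until they contain no accidental run of
#' `min_repeats` or more (so scanners can be scored exactly against the
#' truth), and plant boundaries are checked not to extend the run.
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length in bp.
#' @param gc Background GC fraction.
#' @param plants_per_seq Number of repeats planted in each sequence.
#' @param motif_lengths,repeat_range Motif lengths and repeat-count range
#'   of the plants.
#' @param min_flank Minimum distance of a plant from the sequence ends and
#'   from other plants.
#' @param min_repeats Threshold used for the accidental-run check.
#' @param seed Optional seed.
#' @return A list: `sequences` (named character) and `truth` (tibble
#'   `seq_id`, `motif`, `motif_length`, `n_repeats`, `start`, `end`).
#' @export
generate_ssr_sequences <- function(n_seqs = 5, length = 2000, gc = 0.5,
                                   plants_per_seq = 2, motif_lengths = c(3, 4),
                                   repeat_range = c(5, 12), min_flank = 50,
                                   min_repeats = 5, seed = NULL) {
  seq_len_total <- as.integer(length)
  min_flank <- as.integer(min_flank)
  with_seed(seed, {
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_bg <- function(n) {
      paste(sample(names(base_p), n, replace = TRUE, prob = base_p), collapse = "")
    }
    rand_motif <- function() {
      repeat {
        k <- sample(rep(motif_lengths, 2), 1)
        m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
        if (min_period(m) == k) {
          return(m)
        }
      }
    }
    truth <- list()
    seqs <- character(n_seqs)
    for (si in seq_len(n_seqs)) {
      id <- sprintf("seq%02d", si)
      repeat {
        motifs <- replicate(plants_per_seq, rand_motif())
        reps <- sample_range(repeat_range[1], repeat_range[2], plants_per_seq)
        runs <- strrep(motifs, reps)
        spare <- seq_len_total - sum(nchar(runs)) - (plants_per_seq + 1) * min_flank
        if (spare < 0) abort("sequence length too short for the requested plants")
        extra <- if (spare > 0) {
          tabulate(sample.int(plants_per_seq + 1, spare, replace = TRUE),
            plants_per_seq + 1
          )
        } else {
          rep(0L, plants_per_seq + 1)
        }
        gaps <- min_flank + extra
        pieces <- character(0)
        pos <- 0L
        tt <- list()
        # a junction character equal to the motif character one period away
        # would extend the periodic region and shift its coordinates; force
        # the background characters at both junctions to break the period
        fix_char <- function(bg, at, avoid) {
          if (nchar(bg) >= at && substr(bg, at, at) == avoid) {
            substr(bg, at, at) <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
          }
          bg
        }
        for (pi in seq_len(plants_per_seq)) {
          k <- nchar(motifs[pi])
          bg <- rand_bg(gaps[pi])
          bg <- fix_char(bg, nchar(bg), substr(motifs[pi], k, k))
          if (pi > 1) {
            bg <- fix_char(bg, 1, substr(motifs[pi - 1], 1, 1))
          }
          pieces <- c(pieces, bg, runs[pi])
          tt[[pi]] <- tibble::tibble(
            seq_id = id, motif = canonical_motif(motifs[pi]),
            motif_length = nchar(motifs[pi]), n_repeats = reps[pi],
            start = pos + gaps[pi] + 1L,
            end = pos + gaps[pi] + nchar(runs[pi])
          )
          pos <- pos + gaps[pi] + nchar(runs[pi])
        }
        last_m <- motifs[plants_per_seq]
        tail_bg <- fix_char(rand_bg(gaps[plants_per_seq + 1]), 1, substr(last_m, 1, 1))
        s <- paste(c(pieces, tail_bg), collapse = "")
        tt <- dplyr::bind_rows(tt)
        # accept only if the scanner recovers exactly the plants: no
        # accidental background runs, no junction extensions
        hits <- find_ssrs(stats::setNames(s, id), min_repeats = min_repeats)
        expected <- tt[tt$n_repeats >= min_repeats, ]
        cols <- c("motif", "n_repeats", "start", "end")
        same <- nrow(hits) == nrow(expected) &&
          isTRUE(all.equal(
            as.data.frame(hits[order(hits$start), cols]),
            as.data.frame(expected[order(expected$start), cols]),
            check.attributes = FALSE
          ))
        if (same) {
          seqs[si] <- s
          truth[[si]] <- tt
          break
        }
      }
    }
    names(seqs) <- sprintf("seq%02d", seq_len(n_seqs))
    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  })
}
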