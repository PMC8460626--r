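#' Scan sequences for perfect tri-/tetra-nucleotide tandem repeats
#'
#' Reports every maximal perfect tandem run with at least `min_repeats`
#' copies of a 3 or 4 bp motif. Motifs are canonicalised to the
#' lexicographically smallest rotation over both strands, so a scan of the
#' reverse-complemented input yields the same motif set. Motifs that are
#' themselves periodic (homopolymers, or `ACAC`-type 4-mers with period 2)
#' are not true tri-/tetra-nucleotide repeats and are suppressed. Runs are
#' broken at `N` characters.
#'
#' @param seqs Named character vector of DNA sequences (alphabet `ACGTN`,
#'   case-insensitive), or a `Biostrings::DNAStringSet`. See [read_fasta()].
#' @param min_repeats Minimum number of complete motif copies (default 5).
#' @param motif_lengths Motif lengths to scan (subset of `c(3, 4)`).
#' @return A tibble with one row per repeat run: `seq_id`, `motif`
#'   (canonical), `motif_found` (as read on the given strand), `motif_length`,
#'   `n_repeats`, `start`, `end` (1-based, inclusive, spanning the complete
#'   copies: `end - start + 1 == motif_length * n_repeats`), `flank_left`,
#'   `flank_right` (bases available on either side within the sequence).
#' @export
#' @examples
#' find_ssrs(c(s1 = paste0(strrep("T", 30), strrep("AGAT", 6), strrep("C", 30))))
find_ssrs <- function(seqs, min_repeats = 5, motif_lengths = c(3, 4)) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  stopifnot(all(motif_lengths %in% c(3, 4)), min_repeats >= 2)
  seqs <- toupper(seqs)

  out <- purrr::imap_dfr(seqs, function(s, id) {
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0) {
      abort(sprintf(
        "invalid character '%s' at position %d of %s",
        substr(s, bad, bad), bad, id
      ))
    }
    # split on N, keep offsets
    segs <- segment_acgt(s)
    purrr::map_dfr(seq_len(nrow(segs)), function(r) {
      scan_segment(
        substr(s, segs$from[r], segs$to[r]), segs$from[r] - 1L,
        id, nchar(s), min_repeats, motif_lengths
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      seq_id = character(), motif = character(), motif_found = character(),
      motif_length = integer(), n_repeats = integer(), start = integer(),
      end = integer(), flank_left = integer(), flank_right = integer()
    )
  }
  out
}

segment_acgt <- function(s) {
  if (!grepl("N", s, fixed = TRUE)) {
    return(tibble::tibble(from = 1L, to = nchar(s)))
  }
  r <- gregexpr("[ACGT]+", s)[[1]]
  if (r[1] == -1) {
    return(tibble::tibble(from = integer(), to = integer()))
  }
  tibble::tibble(
    from = as.integer(r),
    to = as.integer(r) + attr(r, "match.length") - 1L
  )
}

scan_segment <- function(seg, offset, id, seqlen, min_repeats, motif_lengths) {
  v <- utf8ToInt(seg)
  L <- length(v)
  purrr::map_dfr(as.integer(motif_lengths), function(k) {
    if (L < k * min_repeats) {
      return(tibble::tibble())
    }
    eq <- v[seq_len(L - k)] == v[(k + 1):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hits <- which(r$values & r$lengths >= k * (min_repeats - 1))
    purrr::map_dfr(hits, function(hidx) {
      a <- starts[hidx] # first position of the periodic region (within seg)
      total <- r$lengths[hidx] + k
      reps <- total %/% k
      motif <- substr(seg, a, a + k - 1)
      if (min_period(motif) < k) {
        return(tibble::tibble())
      }
      start <- offset + a # 1-based in full sequence
      end <- start + k * reps - 1L
      tibble::tibble(
        seq_id = id, motif = canonical_motif(motif), motif_found = motif,
        motif_length = k, n_repeats = reps, start = start, end = end,
        flank_left = start - 1L, flank_right = seqlen - end
      )
    })
  })
}

min_period <- function(motif) {
  k <- nchar(motif)
  v <- utf8ToInt(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && all(v[seq_len(k - d)] == v[(d + 1):k])) {
      return(d)
    }
  }
  k
}

rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1, i - 1))
  }, character(1))
}

#' @rdname find_ssrs
#' @param motif A motif string to canonicalise.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#' @param s Character vector of sequences.
#' @return The reverse complement(s).
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# SantaLucia (1998) unified nearest-neighbor parameters
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

#' Oligonucleotide melting temperature and GC content
#'
#' Nearest-neighbor melting temperature (SantaLucia 1998 unified parameter
#' set) with the entropic salt correction `dS + 0.368 (N-1) ln[Na+]`,
#' evaluated at the given primer and monovalent cation concentrations:
#' `Tm = 1000 dH / (dS_salt + R ln(C/4)) - 273.15`. An approximation to the
#' thermodynamics used by full primer-design programs; rankings between
#' primer candidates, not absolute agreement, are the design contract.
#'
#' @param s Character vector of primer sequences (ACGT).
#' @param conc Total single-strand concentration in M (default 2e-7).
#' @param na Monovalent cation concentration in M (default 0.05).
#' @return Melting temperature(s) in degrees Celsius.
#' @export
primer_tm <- function(s, conc = 2e-7, na = 0.05) {
  vapply(toupper(s), function(x) {
    n <- nchar(x)
    stopifnot(n >= 2)
    pairs <- substring(x, seq_len(n - 1), 2:n)
    dh <- sum(NN_DH[pairs])
    ds <- sum(NN_DS[pairs])
    for (term in c(substr(x, 1, 1), substr(x, n, n))) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1
        ds <- ds - 2.8
      } else {
        dh <- dh + 2.3
        ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (n - 1) * log(na)
    1000 * dh / (ds + 1.987 * log(conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname primer_tm
#' @export
gc_content <- function(s) {
  vapply(toupper(s), function(x) {
    v <- strsplit(x, "")[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# 3'-dimer heuristic: either primer's four 3'-terminal bases complementary
# to any window of the partner
has_dimer <- function(p1, p2) {
  tail1 <- substr(p1, nchar(p1) - 3, nchar(p1))
  tail2 <- substr(p2, nchar(p2) - 3, nchar(p2))
  grepl(revcomp(tail1), p2, fixed = TRUE) || grepl(revcomp(tail2), p1, fixed = TRUE)
}

default_screen <- function() {
  list(
    min_flank = 20, # bp of flanking sequence required on each side
    primer_lengths = 18:22,
    tm_range = c(58, 62), # degrees C
    gc_range = c(0.30, 0.70),
    max_tm_diff = 2, # degrees C between the pair
    product_range = c(80, 400), # design-stage amplicon window, bp
    select_length_range = c(100, 350), # selection-stage amplicon window, bp
    max_candidates_per_side = 25
  )
}

# enumerate primer windows in a flank (plus strand for forward; pass the
# reverse-complemented right flank for reverse primers)
primer_candidates <- function(flank, criteria) {
  n <- nchar(flank)
  grid <- expand.grid(len = criteria$primer_lengths, end = seq_len(n))
  grid <- grid[grid$end - grid$len + 1 >= 1, ]
  if (nrow(grid) == 0) {
    return(tibble::tibble())
  }
  seqs <- substring(flank, grid$end - grid$len + 1, grid$end)
  tm <- primer_tm(seqs)
  gc <- gc_content(seqs)
  ok <- tm >= criteria$tm_range[1] & tm <= criteria$tm_range[2] &
    gc >= criteria$gc_range[1] & gc <= criteria$gc_range[2]
  out <- tibble::tibble(
    primer = seqs, start = grid$end - grid$len + 1, end = grid$end,
    len = grid$len, tm = tm, gc = gc
  )[ok, ]
  if (nrow(out) == 0) {
    return(out)
  }
  out$dev <- abs(out$tm - mean(criteria$tm_range)) +
    abs(out$gc - mean(criteria$gc_range)) * 10 +
    abs(out$len - 20) * 0.5
  out[order(out$dev), ][seq_len(min(nrow(out), criteria$max_candidates_per_side)), ]
}

#' Screen repeat candidates for primer design
#'
#' Applies, in order, the in-silico filter cascade used to whittle raw
#' tandem-repeat hits down to workable markers: sufficient flanking
#' sequence, a primer-window search for 18-22-mers with melting temperature
#' 58-62 degrees C and GC 30-70%, a pair melting-temperature difference of
#' at most 2 degrees C, a 3'-complementarity dimer screen, and the amplicon
#' windows (design stage 80-400 bp; selection stage 100-350 bp -- two
#' distinct windows, both configurable). Each surviving candidate carries
#' its best primer pair and a composite penalty (sum of absolute deviations
#' from the window midpoints: Tm in degrees, 10x GC fraction, half the
#' length deviation, plus the pair Tm difference) used for ranking; each
#' failure records the first criterion it failed.
#'
#' @param candidates A tibble from [find_ssrs()].
#' @param seqs The sequences the candidates were found in (named character
#'   vector or `DNAStringSet`).
#' @param criteria Named list overriding any defaults listed above; see
#'   `msatkin:::default_screen()` for the full set.
#' @return `candidates` with screening columns appended: `pass`,
#'   `first_failed`, `fwd_primer`, `rev_primer`, `tm_fwd`, `tm_rev`,
#'   `tm_diff`, `gc_fwd`, `gc_rev`, `product_size`, `penalty`.
#' @export
screen_candidates <- function(candidates, seqs, criteria = list()) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  seqs <- toupper(seqs)
  crit <- utils::modifyList(default_screen(), criteria)

  fail <- function(row, why) {
    dplyr::bind_cols(row, tibble::tibble(
      pass = FALSE, first_failed = why,
      fwd_primer = NA_character_, rev_primer = NA_character_,
      tm_fwd = NA_real_, tm_rev = NA_real_, tm_diff = NA_real_,
      gc_fwd = NA_real_, gc_rev = NA_real_,
      product_size = NA_integer_, penalty = NA_real_
    ))
  }

  purrr::map_dfr(seq_len(nrow(candidates)), function(r) {
    row <- candidates[r, ]
    s <- seqs[[row$seq_id]]
    if (row$flank_left < crit$min_flank || row$flank_right < crit$min_flank) {
      return(fail(row, "insufficient_flank"))
    }
    left <- substr(s, 1, row$start - 1)
    right <- substr(s, row$end + 1, nchar(s))
    fwd <- primer_candidates(left, crit)
    if (nrow(fwd) == 0) {
      return(fail(row, "no_forward_primer"))
    }
    rev <- primer_candidates(revcomp(right), crit)
    if (nrow(rev) == 0) {
      return(fail(row, "no_reverse_primer"))
    }
    # reverse primer occupies plus-strand window
    # [end + (n_right - rev$end) + 1, end + (n_right - rev$start) + 1]
    n_right <- nchar(right)
    best <- NULL
    seen_pair <- FALSE
    for (fi in seq_len(nrow(fwd))) {
      for (ri in seq_len(nrow(rev))) {
        tm_diff <- abs(fwd$tm[fi] - rev$tm[ri])
        if (tm_diff > crit$max_tm_diff) next
        prod_len <- (row$end + (n_right - rev$start[ri] + 1)) - fwd$start[fi] + 1
        if (prod_len < crit$product_range[1] || prod_len > crit$product_range[2]) next
        if (prod_len < crit$select_length_range[1] || prod_len > crit$select_length_range[2]) next
        seen_pair <- TRUE
        if (has_dimer(fwd$primer[fi], rev$primer[ri])) next
        pen <- fwd$dev[fi] + rev$dev[ri] + tm_diff
        if (is.null(best) || pen < best$penalty) {
          best <- tibble::tibble(
            pass = TRUE, first_failed = NA_character_,
            fwd_primer = fwd$primer[fi], rev_primer = rev$primer[ri],
            tm_fwd = fwd$tm[fi], tm_rev = rev$tm[ri], tm_diff = tm_diff,
            gc_fwd = fwd$gc[fi], gc_rev = rev$gc[ri],
            product_size = as.integer(prod_len), penalty = pen
          )
        }
      }
    }
    if (is.null(best)) {
      return(fail(row, if (seen_pair) "dimer" else "no_compatible_pair"))
    }
    dplyr::bind_cols(row, best)
  })
}

#' Partition candidates into multiplex size groups
#'
#' Splits markers by amplicon size for multiplex PCR design: `short`
#' (< 200 bp), `medium` (200-300 bp, boundaries inclusive) and `long`
#' (> 300 bp). The partition is total and disjoint.
#'
#' @param candidates A tibble with a `product_size` column (e.g. from
#'   [screen_candidates()]); rows without a product size fall back to the
#'   repeat-region length plus both flanking windows.
#' @return `candidates` with a `size_group` factor column.
#' @export
group_for_multiplex <- function(candidates) {
  size <- if ("product_size" %in% names(candidates)) {
    candidates$product_size
  } else {
    NA_integer_
  }
  if (all(is.na(size))) {
    size <- candidates$end - candidates$start + 1 + candidates$flank_left + candidates$flank_right
  }
  candidates$size_group <- factor(
    dplyr::case_when(
      size < 200 ~ "short",
      size <= 300 ~ "medium",
      TRUE ~ "long"
    ),
    levels = c("short", "medium", "long")
  )
  candidates
}
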