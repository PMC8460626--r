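---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatkin)
```

`msatkin` analyses codominant microsatellite genotypes scored as PCR
fragment sizes. This vignette records the statistical models, the numerical
conventions, and the design choices that were genuinely open — the things a
maintainer would otherwise have to reverse-engineer from the code.

## Data model and conventions

A genotype is an *unordered* pair of fragment sizes in bp, including the
primer-flanked region; `{128, 140}` and `{140, 128}` are the same genotype
and are normalised on entry, so no downstream statistic can depend on
allele order (a property the test suite exercises). Missing data is a fully
missing pair; a half-scored genotype is demoted to missing with a warning.
Alleles are **not** binned to the repeat-unit ladder: real panels contain
off-ladder alleles (indels in the flanks), and the published size ranges of
the robin panel are not multiples of the motif everywhere. Sizes outside a
declared locus range warn but do not error, for the same reason.

Individuals carry an explicit `unrelated` flag (default: every non-nestling)
selecting the subset used for population statistics. Nothing is
deduplicated automatically — whether a parent belongs in the "unrelated"
sample is a study decision, not a data property.

The per-locus repeat-unit lengths of the packaged robin panel are inferred
from the allele ladders of the published family genotypes (all pairwise
allele differences at a locus are multiples of 3 or of 4); the original
motif annotations sit in an unpublished supplement.

## Diversity statistics

*Expected heterozygosity* uses the unbiased small-sample form
`H_E = 2N/(2N−1)(1 − Σp²)` — the convention of the software the robin panel
was characterised with. The biased form is a one-line change
(`1 − Σp²`); the unbiased form is never smaller, and needs `N ≥ 2`
(otherwise `NA`).

*Hardy–Weinberg testing* is the exact conditional "probability test": given
the allele counts, an array of genotype counts has probability
`n!·Πm_i!·2^h / ((2n)!·Πn_ij!)`, and the p-value sums the probabilities of
all arrays no more probable than the observed one (ties included, with a
`1e-9` log-scale tolerance so floating-point noise cannot split a tie).
Arrays are enumerated by depth-first search with feasibility pruning; the
search is abandoned beyond a configurable node budget (default `1e6`), or
immediately when both `n > 30` and `k > 5` (where the array space is
hopeless), in favour of Monte-Carlo: the `2n` gene copies are shuffled and
re-paired (default `1e5` draws, seeded), and the p-value is reported with
its binomial standard error. Monomorphic loci report `p = 1` with a
`testable = FALSE` flag rather than disappearing.

*F-statistics* are the Weir–Cockerham (1984) variance-component
estimators. Components are summed over alleles and loci *before* forming
any ratio (never averaged as per-locus ratios), which is what makes the
multi-locus estimate well-behaved at nearly-fixed alleles. Zero
denominators (e.g. fully monomorphic data) yield `NA` plus a flagged row,
not an error. θ may legitimately be slightly negative; on a sample
compared against an exact copy of itself the estimator sits near
`−1/(2(n−1))`, which is why "no differentiation" checks use a few hundred
individuals. Significance is by seeded permutation — gene copies within
samples for `F_IS` (heterozygote-deficit one-sided), whole individuals
between populations for `F_ST` — with the permutation count exposed
(defaults of 1000 in the CLI; the published analyses used 200–280).

*Allelic richness* is hypergeometric rarefaction to `g` gene copies. The
default `g` is the per-locus minimum of typed gene copies across
populations, so loci with missing data rarefy to what was actually typed at
that locus rather than to a panel-wide constant.

*Bonferroni*: `signif(alpha/k, 3)` — three significant digits, the
precision of the published tables (0.05/14 → 0.00357). Both `alpha` and
`k` are arguments because the number of tests is a reporting decision.

## Informativeness

PIC, PI and PI_sibs are closed forms in the frequency moments. The three
non-exclusion probabilities are defined *by enumeration* over the
Hardy–Weinberg genotype space with Mendelian transmission — the candidate
side factorises, so the enumeration is exact and fast for any allele count
— rather than by transcribing the long published closed forms, which is an
easy place to introduce sign errors. The tests verify the enumeration
against a seeded million-trio simulation instead, and the suite asserts
the identities that any correct implementation must satisfy: `NE-I ≡ PI`,
`NE-SI ≡ PI_sibs`, `NE-PP ≤ NE-2P ≤ NE-1P`, `PIC ≤ H_E`.

The closed-form null-allele estimators (Brookfield's
`(H_E−H_O)/(1+H_E)` default; Chakraborty's alternative) will not reproduce
values computed by iterative maximum-likelihood software exactly; signs and
magnitudes agree, and negative estimates (heterozygote excess) are
reported as such.

For the whole-panel row, identity and non-exclusion probabilities multiply
across loci (independence assumption). PIC has no product interpretation,
so the panel summary reports the arithmetic mean and the product under
separate labels instead of silently choosing one.

## Parentage by exclusion

The trio check assumes the mother is a true parent (females are sampled
attending the nest). Per locus: if the offspring shares no allele with the
mother it is a `mother_mismatch` (this takes precedence); otherwise the
paternal-consistent allele set is the offspring allele(s) left over by
some maternal assignment, and the verdict is `father_mismatch` exactly
when the father carries none of them. Missing genotypes make the locus
`untestable` and it leaves both numerator and denominator.

An offspring is `extra_pair` at `n_father_mismatch ≥ 3` (default) with at
most one mother mismatch; fully clean offspring are `within_pair`;
everything between is `unresolved`. The threshold exists because real data
contain sub-threshold discordances — the packaged published families
themselves include a one-repeat-unit paternal mismatch in family MO6
(mutation or typo) and a recurring paternal mismatch at ER40 in family WE8
whose pattern (father scored homozygous, several nestlings scored
homozygous for the other allele) is the classic null-allele signature.
Father mismatches one repeat unit away from a paternal allele are flagged
`near_miss` but never change a verdict: flagging is information,
reclassification would be a model.

## Repeat discovery and primer screening

The scanner reports maximal perfect tandem runs of 3–4 bp motifs with at
least five complete copies, the threshold used when the robin markers were
mined. Coordinates are 0-based half-open internally and 1-based inclusive
in every user-facing table; a run's reported span covers only complete
motif copies. Runs are anchored at the leftmost position of the maximal
periodic region, so a run preceded by a coincidentally matching background
character is reported in that shifted register — the brute-force oracle in
the tests implements the same convention independently. Motifs are
canonicalised to the smallest rotation over both strands; motifs that are
themselves periodic (homopolymers, `ACAC`) are rejected as not being true
tri-/tetra-nucleotide repeats. `N` breaks runs.

Melting temperatures use the SantaLucia (1998) unified nearest-neighbour
parameters with the entropic salt correction `ΔS + 0.368(N−1)ln[Na⁺]`, at
0.2 µM primer and 50 mM monovalent salt. This approximates, but will not
match, the thermodynamics inside full primer-design programs; the design
contract is the *ranking* of candidate primers, not absolute temperatures.
The screening cascade applies, in order: flank length (≥ 20 bp), primer
window search (18–22-mers, Tm 58–62 °C, GC 30–70 %), pair ΔTm ≤ 2 °C, the
amplicon windows, and a 3′-dimer rule (reject when the four 3′-terminal
bases of either primer are complementary to any window of the partner) —
a standard heuristic stated explicitly because the original pipeline names
none. "Maximal PCR efficiency" and "minimal penalty" have no published
formula; both are folded into one composite penalty (sum of absolute
deviations from the window midpoints: Tm in °C, 10× GC fraction, half the
length deviation, plus ΔTm), documented as a surrogate for ranking only.
Two amplicon windows exist deliberately: the design-stage 80–400 bp and
the narrower selection-stage 100–350 bp are distinct criteria in the
original workflow and are exposed as separate keys rather than merged.
Multiplex size groups use closed medium bounds: 200 and 300 bp are
`medium`, matching the stated "200–300 bp".

## The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the robin study design: 14 loci, 9–26
alleles per locus on tri-/tetra-nucleotide ladders, two "unrelated"
samples of 45 and 24 under Balding–Nichols differentiation 0.015, and 7
full families of 4–8 nestlings with a family-level EPP rate of 1/7.
EPP is two-level because the study reports two rates (≈15 % of families,
≈4 % of nestlings): a family is flagged with probability `epp_rate`, one
extra-pair sire is drawn per flagged family (half-sib broods, the pattern
seen in family WE8), and each nestling is his with probability
`epp_nestling_fraction` (default 0.3 ≈ 2 of 7; at least one, so the flag
is meaningful). Allele frequencies are flat-Dirichlet by default
(concentration 1), giving the uneven spectra real loci show; large
concentrations approach equifrequency for calibration work. Null alleles
enter the gene pool at a configurable frequency (heterozygous carriers
appear homozygous, homozygous carriers appear missing) and scoring errors
move an allele one motif step — both logged per event in the truth record.

Deliberately absent: coalescent ancestry, mutation–drift equilibrium,
linkage between loci, allele-frequency differences between social and
extra-pair sires, and age/stage structure. Passing recovery tests on these
simulations therefore shows the *estimators* are right, not that real
robin data meet the model's assumptions; in particular the simulator's
clean Mendelian transmission is exactly what the published families
slightly violate (one mutation-like step, one null-allele pattern), which
is why the exclusion threshold, not the simulator, carries that burden.

Determinism: every stochastic entry point takes a seed and restores the
caller's RNG state; inheritance draws use integer sampling only, so a
seeded simulation is bit-reproducible across platforms.

## Numerical and testing choices

Enumeration bounds (`1e6` nodes for the HWE search), Monte-Carlo defaults
(`1e5` shuffles), and the tie tolerance (`1e-9` on the log scale) are
stated above. Frequencies are validated to sum to 1 within `1e-6` and
re-normalised. The test suite sizes its simulations to make each check
decisive but cheap: oracle equivalence of the HWE test covers *every*
allele-count configuration with up to 6 individuals and 3 alleles against
an independent perfect-matching enumerator; estimator recovery uses
N = 500 (F_IS at f = 0.2, ±0.05), 100 replicates of the 45 + 24 design
(median θ in a band around 0.015), and 200 simulated 7-family studies
(pooled EPP family rate against its exact binomial interval); the
million-trio simulation pins the non-exclusion enumeration at three
standard errors.

## Known limitations

- No likelihood-based (LOD) parentage assignment, candidate-male ranking
  or sibship reconstruction — exclusion against the social pair only.
- Null-allele estimation is closed-form; the iterative ML estimator used
  by common parentage software gives slightly different values.
- Only perfect, uninterrupted repeats are discovered; compound and
  interrupted microsatellites are out of scope.
- The HWE probability test is two-sided by construction; one-sided
  heterozygote-deficit/excess U tests are not implemented.
- Genepop export supports three-digit allele coding only (sizes ≤ 999 bp),
  by design of that format.
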