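---
title: "Designing allele-specific LAMP and CAPS assays from barcode alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing allele-specific LAMP and CAPS assays from barcode alignments}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampdx)
```

## The problem

Closely related medicinal plants — the motivating case is *Rhodiola
crenulata* against its common adulterants *Rh. fastigiata* and
*Rh. kirilowii* — are morphologically hard to tell apart once dried and
processed, yet only one of them may be pharmacopoeia-approved. A practical
field assay needs (i) genomic positions where the target species is fixed
for one base and the other species for another, and (ii) a detection
chemistry that turns that single-base difference into a visible signal.
`lampdx` implements the full desk-side part of that workflow on a
DNA-barcode alignment (typically ITS2): diagnostic-SNP discovery, in-silico
CAPS marker prediction, allele-specific LAMP loop-primer design, and the
quantification/decision analysis of the resulting dual-reaction assay.

## Diagnostic SNP discovery

For a species-labelled alignment we compute, at every position, the
within-group nucleotide diversity of each species and the divergence
between the target group and the pooled remainder. Diversity at a site is
the fraction of sequence pairs that differ there; divergence is the
fraction of differing cross-group pairs (average pairwise difference,
Dxy-style). Two conventions matter and are deliberate:

* **Pairwise deletion.** Gaps and fully undetermined residues (`N`) are
  dropped from a site's denominator rather than counted as differences.
  Sites where a group retains fewer than two usable sequences report `NA`,
  never a misleading 0.
* **Ambiguity codes are conservative.** Two residues count as different
  only when their IUPAC base sets are disjoint: a heterozygous `Y` against
  a `C` is *not* a difference. This keeps hybrid individuals from inflating
  apparent divergence.

The screen then flags positions with divergence above `inter_min`
(default 0.37) and every within-group diversity below `intra_max`
(default 0.19) — both dimensionless fractions in [0, 1] — and merges
flagged sites within `merge_gap` (default 10) positions into candidate
regions. The merge radius is our own choice: diagnostic sites cluster into
regions of a few tens of nucleotides, and 10 positions joins sites of one
cluster without bridging distinct regions. Whether the published
thresholds were originally applied to Dxy-style or pooled-sample diversity
is not decidable from the available description; we default to Dxy because
it is the quantity the thresholds act on most naturally, and expose
`inter_mode = "pooled"` for the alternative.

A site becomes a *fixed diagnostic SNP* when each side's modal allele
reaches the fixation threshold (default 0.95 — database sequences carry
occasional errors, so demanding strict monomorphism across ~150 accessions
would be brittle) and the modal alleles differ. Modal-allele ties are
broken in the fixed order A<C<G<T and are never called fixed. Groups whose
within-group diversity is missing at a site do not veto the screen there.

```{r, eval = FALSE}
aln <- make_species_panel(seed = 0)
prof <- diversity_profile(aln, "Rh_crenulata")
reg <- candidate_regions(prof)
diagnostic_snps(aln, "Rh_crenulata", reg$member_sites[[1]])
```

Base-preference matrices (per-group A/C/G/T frequencies with `2 - H`
information content in bits) back the sequence-logo view of a candidate
region; IUPAC codes are split fractionally over their base sets so a
heterozygote contributes half a count to each allele.

## In-silico CAPS

Two adjacent target-specific cytosines create a BglI recognition site
(`GCCNNNN^NGGC`, an interrupted palindrome) that the comparator alleles
lack. `find_sites()` scans degenerate IUPAC patterns on both strands
(palindromes reported once, overlapping matches all reported),
`digest()` applies every top-strand cut simultaneously to the linear PCR
product, and `differential_digest()` reports which enzymes of a table
separate the two alleles. Fragment lengths use gel-band semantics — they
are computed from top-strand cut positions only, so `n` cuts always give
`n + 1` fragments summing to the molecule length; sticky-end overhangs are
recorded in the enzyme definition but do not affect band lengths. A
heterozygous template shows the union of both alleles' bands
(`hybrid_pattern()`): for the packaged 694-bp amplicon pair, 694 + 462 +
232 bp.

## Allele-specific loop-primer design

A LAMP set amplifies between the outer primers F3/B3 using inner primers
FIP (F1c+F2) and BIP (B1c+B2); the single-stranded loop between B1 and B2
is where a backward loop primer (LB) binds. Placing the diagnostic SNP
cluster in that loop lets one LB variant match the target allele perfectly
while forming mismatches on the comparator allele, delaying its
amplification — the discrimination signal.

`validate_primer_set()` checks externally designed sets (ordering
F3 < F2 < F1 < B1 < B2 < B3, loop placement, strand orientation, exact
sequence identity, Tm and GC windows) rather than re-implementing a
primer-search engine; the search space that matters here — LB placements
inside the loop window — is small enough to enumerate exhaustively, which
`enumerate_loop_candidates()` does for each allele and length (defaults 11
and 17 nt, the two design sizes of interest).

Discrimination is scored per mismatch as *position-class weight ×
broken-pair weight × change multiplier*:

* position classes: terminal = first/last 2 nt, center = middle third
  rounded outward, remainder internal. The published account speaks of
  "5′/3′ ends" and "middle" without widths; these are our fixed widths.
* default weights: center 2.0, internal 1.5, terminal 1.0; broken C–G
  1.5, A–T 1.0; all change multipliers 1.0 except T>A at the center
  (1.25). The literature supports *orderings* (center > terminal, C–G >
  A–T, center T>A > C>T), not magnitudes, so the defaults encode the
  orderings with round numbers, the constructor enforces them, and every
  value is configurable. Scores are positively homogeneous in the weights,
  so uniform rescaling cannot change a ranking.

Ranking ties break by more covered SNPs, then longer primer, then leftmost
placement, then lexicographic sequence — a total order, so results are
independent of enumeration order. Backward-loop candidates are emitted in
synthesis orientation (reverse complement of the top strand) with
coordinates kept top-strand 1-based.

Melting temperatures use the unified nearest-neighbor table (Allawi &
SantaLucia 1997 parameters) with the entropic monovalent-salt correction
`ΔS + 0.368·(N−1)·ln[Na+]` at 50 mM Na+ and 250 nM per strand. Tm windows
default to 55–65 °C for core elements and 50–65 °C for loop primers.

## Quantification, kinetics simulation and the decision engine

Copy numbers follow the standard mass-to-copies formula with the rounded
Avogadro constant 6.02×10²³ for fidelity with bench practice (the
full-precision constant sits behind `exact_avogadro = TRUE`; the relative
difference is 4×10⁻⁴). Standard curves are ordinary least squares of Cq on
log10 copies with censored reactions excluded, plus broom-style `tidy()`
/ `glance()` and inverse prediction.

Cq is a *detection time in minutes* throughout (isothermal chemistry);
cycle-reporting instruments map in with a minutes-per-cycle scalar. The
simulator draws

`Cq = a − b·log10(copies) + c·(T − T_opt)² + s·score + N(0, σ)`

with defaults a = 47 min, b = 3.5 min/log10, T_opt = 62 °C,
c = 0.5 min/°C², s = 15 min per score unit, σ = 0.5 min, detection floor
100 copies, run limit 90 min. These are loose calibrations pinned to the
assay's qualitative anchors — a matched 10⁴-copy reaction reads out at
33 min, inside the 35-min visual window; matched-vs-mismatched gaps exceed
40 min; 62 °C is the strict optimum of a 56–64 °C sweep — and are not
fitted to any instrument trace. The temperature coefficient is our own
single choice to make the optimum strict without pushing matched reactions
past the visual window.

The decision engine calls a sample from the two allele-specific reactions
at a cutoff (default 35 min, boundary inclusive — a borderline Cq exactly
at the cutoff counts positive, a documented choice): target-only positive
→ `target_species`, comparator-only → `other_species`, both → `hybrid`
(both alleles present), neither → `invalid` with advice to re-extract (the
published flowchart leaves the double-negative case undefined; we name it
rather than guess). Censored time gaps are reported as lower bounds
(`> run_limit − matched Cq`), never imputed. Indicator colors map
positives to light blue (HNB) or pink (N-red) and negatives to blue or
yellow.

## What the synthetic fixtures emulate — and what they do not

`make_species_panel()` reproduces the *structure* of the study panel:
three species totalling 149 sequences over a 260-position barcode-length
alignment, the five fixed diagnostic alleles (target C162, C166, C167,
A172, T177 against comparator T, T, T, G, A), 0.5% per-site intraspecific
noise at non-diagnostic sites, and optional hybrids carrying the covering
IUPAC code (e.g. Y at a C/T site) at every diagnostic position. The
background is random uniform sequence: real ITS2 has conserved cores,
indel structure and phylogenetic correlation between accessions, none of
which the generator models. Passing screens on these panels therefore
demonstrates the *arithmetic* of the method — thresholding, merging,
fixation logic — not its robustness to alignment error or sampling bias in
real databases.

`make_amplicon_pair()` embeds exactly one BglI site in a random 694-bp
amplicon so the top-strand cut falls after position 232, and destroys it
in the comparator allele (C→T at both allele-specific site bases). It
reproduces the band arithmetic (232/462/694), not the real amplicon's
sequence context, whose alignment-to-amplicon offset is not recoverable
from the published material. By default the pair differs at only those two
bases; `extra_snps = TRUE` (used by `make_lamp_fixture()`) also embeds the
other three diagnostic differences so loop-primer design sees the full
cluster. `make_lamp_fixture()` places geometry-legal primer intervals
around the cluster and resamples their free bases until every validation
rule passes — a constructed-to-pass fixture, not a thermodynamic search —
then re-verifies that no second restriction site appeared.

All generators are deterministic functions of their seed.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere.
* Ragged alignments, unknown residue codes, unlabeled sequences and empty
  groups are rejected at construction, not discovered downstream.
* Digestion requires unambiguous input (a degenerate template has no
  single band pattern); diversity handles the full IUPAC alphabet.
* Windowed diversity (width > 1) averages per-site values over windows
  anchored at their start; counts are summed.
* Frequencies summing to 1 are asserted to 10⁻⁹; Tm is deterministic to
  machine precision.

## Problem sizes

The test-suite and reproduction-script workloads are sized for a desk run:
149-sequence × 260-position panels, 694-bp amplicon pairs, ~120-candidate
loop enumerations, 6-level × 3-replicate dilution series, and a 20-seed
end-to-end sweep — each full pipeline pass takes about a second.

## Known limitations

* No multiple-sequence alignment, chromatogram parsing, or GenBank
  retrieval: input alignments are taken as given.
* No de-novo LAMP set search, secondary-structure/dimer thermodynamics, or
  dye chemistry modelling; primer sets from a design tool are validated,
  only loop primers are enumerated.
* No partial-digestion or methylation modelling in CAPS.
* The kinetics simulator is phenomenological; its parameters are
  calibration knobs, not estimates, and conclusions about real sensitivity
  or specificity must come from bench data.
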