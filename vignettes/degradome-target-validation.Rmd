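---
title: "Validating small RNA targets from degradome data with pared"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating small RNA targets from degradome data with pared}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pared)
```

## The problem

Plant miRNAs silence their targets predominantly by AGO-mediated slicing
of the mRNA between the nucleotides paired to miRNA positions 10 and 11.
Degradome (PARE) sequencing captures the 5′ ends of the uncapped 3′
cleavage fragments, so a degradome read whose 5′ end coincides with the
predicted slice site of a miRNA:target duplex is direct physical evidence
of targeting. `pared` implements this validation end to end: read
cleaning, transcriptome alignment, cleavage-profile construction and
categorisation, duplex scoring, a stringent filter stack, cross-sample
comparison, and detection of 21-nt phased secondary siRNAs (tasiRNAs /
phasiRNAs) triggered by a validated cleavage event, including validation
of the secondary siRNAs' own targets — the cascade of silencing.

Two design choices distinguish the pipeline from the classic
CleaveLand-style analysis, and both concern *multiplicity*:

1. **All-placement alignment.** Each degradome read is reported at every
   transcript position it matches within the mismatch budget. Gene
   families often share the cut-site sequence; a single-placement aligner
   silently attributes the shared read to one member and hides the rest.
2. **Multi-target retention.** All duplex sites passing the filters are
   kept — never one best-MFE-ratio target per miRNA. A compatibility
   switch (`collapse_to_best_mfe = TRUE` in `validate_targets()`)
   restores the classic one-per-miRNA behaviour for regression
   comparison.

## Read preprocessing

Degradome libraries are single-end; MmeI digestion during library
construction releases 20–21-nt tags. Preprocessing is deliberately
minimal and exactly reproducible:

* 3′ adapter removal: the leftmost exact occurrence of the adapter
  (default `TGGAATTCTCGGGTGCCAAGGAA`), or of at least
  `min_adapter_overlap = 6` of its leading bases as a read suffix. No
  mismatches are tolerated in the adapter match and no quality trimming
  is performed. Reads without any qualifying match never reached the
  adapter and are discarded.
* t/rRNA removal by exact (sub)string matching against a contaminant set.
* Size selection to 20–21 nt (20–24 nt for sRNA libraries feeding the
  phasing stage). Whether 22-nt MmeI tags should be admitted is exposed
  through the config; the default window is 20–21.
* Reads containing `N` are dropped before alignment: the aligner treats
  `N` as a mismatch everywhere, which inflates spurious multi-mapping.

Libraries from several tissues of one genotype are merged
(`merge_libraries()`) before profiling, so cleavage categories are
assigned on the pooled per-species signal.

## Alignment

`build_index()` / `align_read()` implement exact seed-and-verify
alignment with a pigeonhole guarantee: a read with at most *m* mismatches
must contain one of *m* + 1 disjoint exact k-mers, so every placement
within the budget is found — there is no best-hit selection and no
heuristic loss. Defaults are one mismatch for degradome reads against
cDNA and zero mismatches for sRNAs in the phasing stage. Degradome reads
align to the sense strand only (they are fragments of the mRNA itself);
sRNAs align to both strands, since phased siRNAs derive from a
double-stranded RDR6 product. Multi-mapped reads contribute their full
count at every placement; fractional weighting would re-suppress exactly
the paralogs the all-placement design is meant to recover. The
reads-per-million denominator counts each read once, regardless of its
number of placements.

## Cleavage profiles and categories

For every transcript, `build_profile()` tallies degradome 5′ ends per
position. Occupied positions are ranked by the standard category scheme,
computed on raw counts (RPM is reported alongside):

| category | definition |
|---|---|
| 1 | count > 1, equal to the transcript maximum (unique or tied) |
| 2 | count > 1, above the mean over occupied positions, below the maximum |
| 3 | count > 1, at or below the occupied mean |
| 4 | exactly one read |

The two historical maximum classes (unique maximum, category 0, and tied
maximum, category 1) are merged into category 1. Three boundary
conventions are fixed exactly as worded in the scheme's definitions:
"below the maximum" is strict, "below or equal to the average" is
inclusive, and a count-1 position is category 4 even when it happens to
equal the transcript maximum, because the maximum classes require more
than one read.

## Duplex scoring

`enumerate_duplexes()` aligns the small RNA antiparallel against every
transcript window, allowing up to two bulged nucleotides on either
strand but none at positions 10–11, where slicing requires intact
pairing. The bound of two keeps the search exhaustively enumerable; the
enumeration is implemented in C++ and verified against a brute-force
window/bulge oracle in the test suite.

The **Allen score** is the additive complementarity penalty: mismatch 1,
G:U wobble 0.5, each bulged nucleotide 1, all doubled at miRNA positions
2–13 (position 1 = 5′ end). All constants and the doubling window are
exposed via `allen_params()`.

The **MFE ratio** is the duplex hybridisation energy divided by the
energy of the perfect complement of the same small RNA. Energies come
from an internal nearest-neighbour stack model: published Watson–Crick
stack free energies, G:U-containing stacks geometrically weakened
(`gu_scale = 0.4` per wobble pair in a stack), fixed interior-loop and
bulge penalties (1.7 and 3.5 kcal/mol per nucleotide), duplex initiation
(+4.09 kcal/mol) and terminal A:U/G:U penalties (+0.45). Because every
paired target base is implied by the miRNA base, the energy is a
function of the miRNA sequence and the pairing string alone. The model
is intentionally simple — the ratio, not the absolute energy, enters the
filters — and `enumerate_duplexes(mfe_fun = ...)` accepts externally
computed energies (e.g. from an RNAplex run) when reconciliation with
another backend is wanted. Overlapping candidate windows are reduced to
the locally best site (minimum Allen score, ties broken by maximum MFE
ratio, then leftmost), and the predicted cleavage coordinate is the
transcript position paired with miRNA position 10 — the expected 5′ end
of the degradome read.

## Validation and filtering

A duplex hit becomes a target record when a degradome 5′ end lies within
±1 nt of the predicted cleavage coordinate (degradome ends wobble by a
nucleotide; the window is configurable, and the matched position's
count, RPM and category attach to the record). The stringent tier keeps
records with Allen score ≤ 4, MFE ratio ≥ 0.69 and miRNA abundance
≥ 0.5 RPM — all boundaries inclusive, since targets are reported *at*
score 4 and ratio 0.69. Records up to Allen 5 are retained as a looser
candidate tier. `compare_samples()` groups records into miRNA families
by identical mature sequence (after U/T canonicalisation) and keys
pairs on (family, transcript); matching on the transcript rather than
the exact cut site makes cross-sample overlap robust to ±1-nt cut-site
wobble, and the per-sample categories are reported side by side.

## Phased secondary siRNAs

Downstream of a validated cleavage anchor, `phase_scan()` tests each of
the 21 possible phase registers over a 189-nt window (9 cycles of
21 nt). Occupancy is positional: distinct 5′-end positions with summed
abundance ≥ 1, from zero-mismatch 21-nt alignments; abundances gate
occupancy but do not otherwise enter the statistic. Minus-strand reads
are projected onto the plus-strand lattice with the 2-nt 3′-overhang
correction of the dicing duplex. Significance is the exact
hypergeometric tail

$$P(X \ge k) = \sum_{x=k}^{\min(n,m)} \frac{\binom{m}{x}\binom{L-m}{n-x}}{\binom{L}{n}},$$

with $L$ the window length, $m$ the lattice positions, $n$ the occupied
positions and $k$ the phased ones. A perfect 9-cycle ladder gives
$p = 1/\binom{189}{9} \approx 1.4\times10^{-15}$. Phased reads of
significant registers (default cutoff $p \le 0.01$) are named by their
cycle — D1 is the first full 21-nt cycle 3′ of the cut site, minus-strand
partners carry the cycle of the duplex they complement — and re-enter
duplex scoring as secondary siRNAs, validated against the whole
transcriptome with the same stringent cut-offs. Secondary siRNAs
routinely re-target their own parent transcript and its family members;
all such records are kept and tagged `secondary`.

When no trigger is known the anchor can be slid; note that scanning all
21 registers inflates the family-wise false-positive rate above the
per-register level (the per-register tail is exact and conservative),
so anchored scans are preferred whenever a validated trigger exists.

## Synthetic data and what passing tests mean

`make_golden_fixture()` generates a fully specified miniature study:
three paralogous ~800-nt transcripts sharing an identical 42-nt
cut-site block (site plus downstream sequence, so the 20–21-nt cut-site
read multi-maps to all three), a TAS-like transcript whose trigger site
carries one 3′-region mismatch, a 9-cycle phased ladder with two
minus-strand partners and off-lattice noise, a downstream ARF-like
target of one phased siRNA, degradome peaks (30 reads) at every planted
cleavage site and a uniform background whose 5′ ends avoid planted
neighbourhoods, so planted categories cannot be perturbed. A single seed
drives all randomness; the same seed reproduces the fixture
byte-identically. The shipped copy under `inst/extdata/golden/` was
written with seed 1814.

The generator emulates 5′-end peak structure, family-shared cut sites
and phase ladders, but not sequencing error, expression-dependent
coverage gradients, RNA structure or partial degradation. Passing the
end-to-end tests therefore demonstrates correctness of the algorithms
under the stated model, not performance on real tissue libraries.

Problem sizes used in the checks: 10,000 random profiles for the
category oracle, 100 random miRNA × (≤500 nt) transcript pairs for the
duplex-search oracle, full enumeration of occupancy patterns up to
$L = 42, n \le 6$ for the phasing statistic, and 1,000 simulations for
its calibration.

## Numerical and degenerate-input conventions

* Coordinates are 1-based and inclusive throughout; U and T are
  canonicalised at parse time.
* Duplexes whose model energy is non-negative are rejected outright
  (this also removes sub-minimal helices such as single-pair "duplexes").
* Site-reduction ties are broken deterministically (Allen, then ratio,
  then leftmost, then shortest), so runs are bit-stable; TSV exports
  format floats to six decimals.
* Empty inputs (no reads, no hits, empty contaminant set) propagate as
  empty results, never errors; a p-value request with inconsistent
  counts ($k > \min(n,m)$ or $n > L$) is an error.
* An anchor outside the transcript is an error; a window truncated by
  the transcript end shrinks $L$ and $m$ accordingly.

## Known limitations

* The internal energy model is a stack-level approximation; absolute
  energies differ from full Turner-model calculators, which matters only
  if externally computed ratios are mixed with internal ones in a single
  run (use the `mfe_fun` hook consistently instead).
* The aligner targets transcriptomes, not genomes: no splicing, no
  indels within reads.
* Indexing assumes reads of at least `seed_k` nt; shorter reads fall
  back to exhaustive verification.
* The documented mismatch budgets (1 for degradome reads, 0 for sRNAs)
  are defaults, not mandates; both are config keys. Reported analyses
  with other tools have used budgets up to 2, so comparisons should
  state the budget used.
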